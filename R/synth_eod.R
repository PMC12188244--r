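# Synthetic biphasic pulse generator.
#
# The model pulse is deliberately not a biophysical electrocyte simulation:
# it is a head-positive raised-cosine bump (P1), an adjacent head-negative
# raised-cosine falling edge (P2), and an exact exponential recovery
# a * exp(-tau * (t - tP2)) after the P2 minimum, continuous at the junction.
# With this construction every landmark the waveform module measures (start,
# zero-crossing, peak/trough times, threshold- and window-rule end points,
# maximum P1 slope, tau) has a closed form, so detector output can be checked
# against analytic truth rather than against a second implementation.

#' Parameters of the synthetic biphasic EOD pulse
#'
#' Defaults emulate an untreated adult *Brienomyrus brachyistius* EOD under
#' the recording settings used throughout the package (250 kHz, 2048 points):
#' normalized amplitudes vP1 = 0.41 / vP2 = -0.59, P2 recovery constant
#' tau = 31.06 per ms, and phase widths calibrated so the detected EOD
#' duration (0.5% threshold rules) is 0.68 ms.
#'
#' @param a1,a2 P1 / P2 amplitudes (positive; only `a1/(a1+a2)` survives
#'   peak-to-peak normalization).
#' @param t1 centre of the P1 bump (ms from snippet start).
#' @param w1 P1 half-width (ms); P1 support is `[t1 - w1, t1 + w1]`.
#' @param w2 width of the P2 falling edge (ms); it spans `[t2 - w2, t2]`.
#' @param t2 time of the P2 minimum (ms). Phases must not overlap:
#'   `t1 + w1 <= t2 - w2`. The default places P2 immediately after P1.
#' @param tau exponential recovery rate constant (per ms, > 0).
#' @param offset constant baseline voltage added to every sample (V).
#' @param noise_sd additive Gaussian noise s.d., in normalized units. The
#'   default 0.005 sits exactly at the 0.5% detection threshold so the
#'   detectors are exercised under stress.
#' @param sample_rate sampling rate in Hz.
#' @param npts samples per snippet.
#' @return an object of class `eod_pulse_params`.
#' @seealso [simulate_eod_snippet()], [pulse_truth()]
#' @export
eod_pulse_params <- function(a1 = 0.41, a2 = 0.59, t1 = 3.0, w1 = 0.17,
                             w2 = 0.176, t2 = t1 + w1 + w2, tau = 31.06,
                             offset = 0, noise_sd = 0.005,
                             sample_rate = 250000, npts = 2048) {
  p <- list(a1 = a1, a2 = a2, t1 = t1, t2 = t2, w1 = w1, w2 = w2, tau = tau,
            offset = offset, noise_sd = noise_sd, sample_rate = sample_rate,
            npts = as.integer(npts))
  for (f in c("a1", "a2", "w1", "w2", "tau"))
    stop_unless(is_num1(p[[f]]) && p[[f]] > 0, "'%s' must be positive", f)
  stop_unless(is_num1(t1) && is_num1(t2) && t1 < t2, "'t1' must precede 't2'")
  stop_unless(t1 + w1 <= t2 - w2 + 1e-12,
              "P1 and P2 overlap (t1 + w1 > t2 - w2); closed-form truth requires disjoint phases")
  stop_unless(is_num1(p$sample_rate) && p$sample_rate > 0,
              "'sample_rate' must be positive")
  stop_unless(is_count(p$npts) && p$npts >= 1024,
              "'npts' must be at least twice the 512-sample baseline window")
  stop_unless(is_num1(noise_sd) && noise_sd >= 0, "'noise_sd' must be >= 0")
  stop_unless(is_num1(offset), "'offset' must be a finite number")
  class(p) <- "eod_pulse_params"
  p
}

# piecewise model, noise- and offset-free, t in ms
pulse_model <- function(t, p) {
  v <- numeric(length(t))
  i1 <- abs(t - p$t1) <= p$w1
  v[i1] <- p$a1 * cos(pi * (t[i1] - p$t1) / (2 * p$w1))^2
  i2 <- t >= (p$t2 - p$w2) & t < p$t2
  v[i2] <- -p$a2 * cos(pi * (t[i2] - p$t2) / (2 * p$w2))^2
  i3 <- t >= p$t2
  v[i3] <- -p$a2 * exp(-p$tau * (t[i3] - p$t2))
  v
}

#' Closed-form landmark truth for a synthetic pulse
#'
#' All quantities are expressed on the normalized (peak-to-peak = 1) scale
#' the waveform module measures on. Two end points are reported:
#' `t_end_threshold`, where the recovering tail itself crosses the negative
#' threshold, and `t_end_rule`, the continuous-time solution of the trailing
#' `end_window`-point mean rule actually applied by [detect_bounds()] (the
#' windowed mean of a growing exponential crosses the threshold later by
#' `log(G)/tau`, with `G` the window's geometric correction factor).
#' `duration` is defined from `t_end_rule`, i.e. it is the value the paper's
#' detector measures on a noise-free pulse.
#'
#' @param params an [eod_pulse_params()] object.
#' @param cfg a [detection_config()]; the truth depends on its threshold
#'   fraction and end-window length.
#' @return a list of landmark times (ms, absolute within the snippet),
#'   normalized amplitudes, `sp1` (normalized units per ms) and durations.
#' @export
pulse_truth <- function(params, cfg = detection_config()) {
  A1 <- params$a1 / (params$a1 + params$a2)
  A2 <- params$a2 / (params$a1 + params$a2)
  thr <- cfg$threshold_frac
  stop_unless(thr < A1 && thr < A2,
              "threshold fraction exceeds a phase amplitude; pulse undetectable")
  dtm <- 1000 / params$sample_rate
  t_start <- params$t1 - (2 * params$w1 / pi) * acos(sqrt(thr / A1))
  t_zc <- params$t1 + params$w1
  W <- cfg$end_window
  G <- mean(exp(params$tau * dtm * (0:(W - 1))))
  t_end_rule <- params$t2 + log(A2 * G / thr) / params$tau
  t_end_threshold <- params$t2 + log(A2 / thr) / params$tau
  snip <- (params$npts - 1) * dtm
  if (t_start <= 0 || t_end_rule >= snip)
    stop("pulse not contained in snippet: truth crossings outside [0, npts*dt]",
         call. = FALSE)
  list(
    t_start = t_start, t_zerocross = t_zc,
    t_vp1 = params$t1, t_vp2 = params$t2,
    t_end_rule = t_end_rule, t_end_threshold = t_end_threshold,
    v_vp1 = A1, v_vp2 = -A2,
    duration = t_end_rule - t_start,
    p1_duration = t_zc - t_start,
    p2_duration = t_end_rule - t_zc,
    p1p2_delay = params$t2 - params$t1,
    vp2_vp1_ratio = -A2 / A1,
    sp1 = A1 * pi / (2 * params$w1),
    tau = params$tau
  )
}

#' Simulate one EOD snippet
#'
#' Evaluates the piecewise pulse model on the sampling grid, adds the
#' baseline offset and (optionally) white Gaussian noise, and attaches the
#' closed-form landmark truth.
#'
#' @param params an [eod_pulse_params()] object.
#' @param seed optional integer; when given, `set.seed(seed)` precedes the
#'   noise draw so identical calls are bit-identical. When `NULL` the current
#'   RNG stream is consumed (used by [simulate_cohort()]).
#' @param metadata free-form list (fish id, treatment, day, ...).
#' @param cfg detection configuration used for the attached truth.
#' @return an object of class `eod_recording`: fields `samples` (volts),
#'   `dt` (s), `metadata`, and `truth` (see [pulse_truth()]).
#' @examples
#' rec <- simulate_eod_snippet(eod_pulse_params(noise_sd = 0), seed = 1)
#' rec$truth$duration
#' @export
simulate_eod_snippet <- function(params = eod_pulse_params(), seed = NULL,
                                 metadata = list(), cfg = detection_config()) {
  truth <- pulse_truth(params, cfg)
  dtm <- 1000 / params$sample_rate
  t <- (seq_len(params$npts) - 1) * dtm
  v <- pulse_model(t, params)
  if (!is.null(seed)) set.seed(seed)
  if (params$noise_sd > 0)
    v <- v + rnorm(params$npts, 0, params$noise_sd * (params$a1 + params$a2))
  v <- v + params$offset
  structure(list(samples = v, dt = 1 / params$sample_rate,
                 metadata = metadata, truth = truth, params = params),
            class = "eod_recording")
}

#' @export
print.eod_recording <- function(x, ...) {
  cat(sprintf("<eod_recording> %d samples @ %.0f kHz", length(x$samples),
              1e-3 / x$dt))
  if (length(x$metadata))
    cat(" |", paste(names(x$metadata), unlist(x$metadata), sep = "=",
                    collapse = " "))
  cat("\n")
  invisible(x)
}

#' Treatment-cohort design for the pulse simulator
#'
#' Defaults reproduce the study structure: control n = 6 (days 0-8),
#' T1day n = 7 (days 0-1), T8day n = 7 (days 0-8), with androgen-induced
#' elongation modelled as a linear ramp of the time-axis multiplier from 1.0
#' at day 0 to 1.96 at day 8, applied to T8day fish only (T1day fish are
#' sampled before their waveform responds). Between-fish variability scales
#' the whole time axis (CV 0.19, matching a 0.13 ms s.d. on a 0.68 ms
#' duration); day-to-day jitter has CV 0.02, comfortably inside the < 5%
#' acclimation criterion.
#'
#' @param groups named integer vector of fish per treatment; names must be a
#'   subset of `control`, `T1day`, `T8day`.
#' @param days named list of recording days per treatment (default: 0-8 for
#'   control and T8day, 0-1 for T1day).
#' @param snippets_per_session EOD snippets recorded per fish per day.
#' @param multiplier_end T8day duration multiplier reached at `ramp_days`.
#' @param ramp_days days over which the multiplier ramps linearly.
#' @param base baseline [eod_pulse_params()] for an untreated fish.
#' @param between_fish_cv,day_cv,amp_sd variability knobs (time-axis scale
#'   between fish, daily jitter, s.d. of the per-fish normalized vP1).
#' @param seed integer seed; the whole cohort derives from it.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(control = 6, T1day = 7, T8day = 7),
                          days = NULL, snippets_per_session = 10,
                          multiplier_end = 1.96, ramp_days = 8,
                          base = eod_pulse_params(),
                          between_fish_cv = 0.19, day_cv = 0.02,
                          amp_sd = 0.03, seed = 1) {
  stop_unless(length(groups) >= 1 && all(groups >= 1),
              "group sizes must be >= 1")
  bad <- setdiff(names(groups), EOD_TREATMENTS)
  stop_unless(length(bad) == 0, "unknown treatment label: %s",
              paste(bad, collapse = ", "))
  if (is.null(days)) {
    days <- list(control = 0:8, T1day = 0:1, T8day = 0:8)[names(groups)]
  }
  stop_unless(all(names(groups) %in% names(days)),
              "'days' must name every treatment in 'groups'")
  stop_unless(is_num1(multiplier_end) && multiplier_end >= 1,
              "'multiplier_end' must be >= 1 (non-decreasing trajectory)")
  stop_unless(is_count(snippets_per_session), "'snippets_per_session' invalid")
  structure(list(groups = groups, days = days,
                 snippets_per_session = as.integer(snippets_per_session),
                 multiplier_end = multiplier_end, ramp_days = ramp_days,
                 base = base, between_fish_cv = between_fish_cv,
                 day_cv = day_cv, amp_sd = amp_sd, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Duration multiplier for a treatment/day
#'
#' 1 for every treatment on or before day 0 and for control/T1day fish
#' throughout; linear ramp to `multiplier_end` for T8day fish.
#'
#' @param design a [cohort_design()].
#' @param treatment,day treatment label and experiment day.
#' @export
duration_multiplier <- function(design, treatment, day) {
  ifelse(treatment == "T8day" & day > 0,
         1 + (design$multiplier_end - 1) *
           pmin(day, design$ramp_days) / design$ramp_days,
         1)
}

# pulse parameters for one fish-day: time axis scaled by k, tau by 1/k
scale_pulse_params <- function(base, k, a1) {
  tot <- base$a1 + base$a2
  eod_pulse_params(a1 = a1, a2 = tot - a1, t1 = base$t1,
                   w1 = base$w1 * k, w2 = base$w2 * k,
                   t2 = base$t1 + (base$t2 - base$t1) * k,
                   tau = base$tau / k, offset = base$offset,
                   noise_sd = base$noise_sd, sample_rate = base$sample_rate,
                   npts = base$npts)
}

#' Simulate a full treatment cohort of EOD recordings
#'
#' Draws a per-fish time-axis scale and P1 amplitude, then per recording day
#' applies daily jitter and the treatment's duration multiplier and simulates
#' `snippets_per_session` noisy snippets. Intended (noise-free, closed-form)
#' per-fish per-day truth accompanies the recordings.
#'
#' @param design a [cohort_design()].
#' @return object of class `eod_cohort`: `recordings[[fish]][[as.character(day)]]`
#'   is a list of `eod_recording`s; `truth` is a data frame with one row per
#'   fish-day (intended duration, tau, multiplier, scale, ...).
#' @examples
#' co <- simulate_cohort(cohort_design(groups = c(control = 2, T8day = 2),
#'                                     days = list(control = c(0, 8),
#'                                                 T8day = c(0, 8)),
#'                                     snippets_per_session = 2, seed = 7))
#' head(co$truth)
#' @export
simulate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  recordings <- list()
  rows <- list()
  for (tr in names(design$groups)) {
    for (f in seq_len(design$groups[[tr]])) {
      fish <- sprintf("%s_f%02d", tr, f)
      k_f <- min(max(rnorm(1, 1, design$between_fish_cv), 0.5), 1.6)
      tot <- design$base$a1 + design$base$a2
      a1_f <- min(max(rnorm(1, design$base$a1, design$amp_sd * tot),
                      0.25 * tot), 0.55 * tot)
      recordings[[fish]] <- list()
      for (day in design$days[[tr]]) {
        k_d <- k_f * max(rnorm(1, 1, design$day_cv), 0.5) *
          duration_multiplier(design, tr, day)
        p_fd <- scale_pulse_params(design$base, k_d, a1_f)
        tru <- pulse_truth(p_fd)
        md <- list(fish = fish, treatment = tr, day = day)
        snips <- lapply(seq_len(design$snippets_per_session), function(s) {
          simulate_eod_snippet(p_fd, seed = NULL,
                               metadata = c(md, list(snippet = s)))
        })
        recordings[[fish]][[as.character(day)]] <- snips
        rows[[length(rows) + 1L]] <- data.frame(
          fish = fish, treatment = tr, day = day,
          multiplier = duration_multiplier(design, tr, day),
          scale = k_d, duration = tru$duration,
          p1_duration = tru$p1_duration, p2_duration = tru$p2_duration,
          p1p2_delay = tru$p1p2_delay, tau = tru$tau,
          vp1 = tru$v_vp1, vp2 = tru$v_vp2,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(recordings = recordings,
                 truth = do.call(rbind, rows), design = design),
            class = "eod_cohort")
}

#' @export
print.eod_cohort <- function(x, ...) {
  cat(sprintf("<eod_cohort> %d fish, %d fish-days, %d snippets/session\n",
              length(x$recordings), nrow(x$truth),
              x$design$snippets_per_session))
  invisible(x)
}
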