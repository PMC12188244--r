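# EOD waveform preprocessing, landmark detection and feature extraction.
#
# The measurement conventions follow the standard pulse-EOD protocol:
# per-snippet baseline correction with the pooled mean of the first and last
# `baseline_window` samples, peak-to-peak normalization, alignment at the
# maximum head-positive voltage (vP1, assigned time 0), snippet averaging,
# threshold rules at 0.5% of peak-to-peak for the pulse bounds, and an
# exponential decay fit y = a*exp(-tau*t) + b between the P2 minimum and the
# pulse end.

#' Detection configuration for the waveform module
#'
#' @param baseline_window samples taken from each end of the snippet for
#'   baseline estimation (default 512).
#' @param threshold_frac detection threshold as a fraction of peak-to-peak
#'   amplitude, in (0, 0.5) (default 0.005, i.e. 0.5%).
#' @param start_run consecutive supra-threshold samples required to call the
#'   pulse start (default 3).
#' @param end_window trailing window length for the end rule (default 11):
#'   the pulse ends at the first sample whose previous `end_window`-point
#'   mean voltage exceeds the negative threshold.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(baseline_window = 512, threshold_frac = 0.005,
                             start_run = 3, end_window = 11) {
  stop_unless(is_count(baseline_window), "'baseline_window' must be a positive integer")
  stop_unless(is_num1(threshold_frac) && threshold_frac > 0 &&
                threshold_frac < 0.5, "'threshold_frac' must be in (0, 0.5)")
  stop_unless(is_count(start_run), "'start_run' must be a positive integer")
  stop_unless(is_count(end_window), "'end_window' must be a positive integer")
  structure(list(baseline_window = as.integer(baseline_window),
                 threshold_frac = threshold_frac,
                 start_run = as.integer(start_run),
                 end_window = as.integer(end_window)),
            class = "detection_config")
}

#' Preprocess and average EOD snippets
#'
#' Per snippet: subtract the pooled mean of the first and last
#' `baseline_window` samples, divide by the peak-to-peak amplitude, and shift
#' so the maximum (vP1) sits at time 0. Aligned snippets are then averaged
#' sample-wise on the overlapping grid and the average is re-normalized to
#' peak-to-peak 1.
#'
#' @param recordings an `eod_recording` or list of them (equal `npts`/`dt`).
#' @param cfg a [detection_config()].
#' @return object of class `aligned_waveform`: `values` (normalized),
#'   `time` (ms, 0 at the vP1 sample), `dt` (s), `n_averaged`, and
#'   `origin_ms`, the absolute snippet time of the first snippet's peak
#'   (lets callers map aligned times back to snippet time).
#' @export
preprocess_recordings <- function(recordings, cfg = detection_config()) {
  if (inherits(recordings, "eod_recording")) recordings <- list(recordings)
  stop_unless(length(recordings) >= 1, "need at least one recording")
  npts <- length(recordings[[1]]$samples)
  dt <- recordings[[1]]$dt
  for (r in recordings) {
    stop_unless(length(r$samples) == npts && isTRUE(all.equal(r$dt, dt)),
                "recordings must share npts and dt")
    stop_unless(all(is.finite(r$samples)), "non-finite sample values")
  }
  bw <- cfg$baseline_window
  stop_unless(npts >= 2 * bw, "npts must be >= 2 * baseline_window")
  peaks <- integer(length(recordings))
  norm <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    v <- recordings[[i]]$samples
    v <- v - mean(v[c(seq_len(bw), (npts - bw + 1):npts)])
    ptp <- max(v) - min(v)
    if (ptp <= 0) stop("flat snippet: zero peak-to-peak amplitude", call. = FALSE)
    v <- v / ptp
    peaks[i] <- which.max(v)
    norm[[i]] <- v
  }
  L <- min(peaks) - 1L
  R <- npts - max(peaks)
  if (L < 1L || R < 1L)
    stop("alignment would push the pulse outside the overlapping window",
         call. = FALSE)
  mat <- vapply(seq_along(norm),
                function(i) norm[[i]][(peaks[i] - L):(peaks[i] + R)],
                numeric(L + R + 1L))
  avg <- rowMeans(mat)
  avg <- avg / (max(avg) - min(avg))
  structure(list(values = avg,
                 time = ((-L):R) * dt * 1000,
                 dt = dt, n_averaged = length(recordings),
                 origin_ms = (peaks[1] - 1L) * dt * 1000),
            class = "aligned_waveform")
}

#' Locate the amplitude landmarks of an aligned waveform
#'
#' vP1 is the global maximum (time 0 by alignment), vP2 the global minimum,
#' and the P1-to-P2 zero crossing is linearly interpolated between the
#' bracketing samples.
#'
#' @param w an [preprocess_recordings()] result.
#' @return object of class `eod_landmarks` with `t_vp1`, `t_vp2`, `v_vp1`,
#'   `v_vp2`, `t_zerocross` (ms) and sample indices `i_vp1`, `i_vp2`.
#' @export
find_landmarks <- function(w) {
  stopifnot(inherits(w, "aligned_waveform"))
  v <- w$values
  i1 <- which.max(v)
  i2 <- which.min(v)
  if (!(v[i1] > 0 && v[i2] < 0) || i2 <= i1)
    stop("not a biphasic pulse: no negative phase after the positive peak",
         call. = FALSE)
  j <- NA_integer_
  for (k in i1:(i2 - 1L)) {
    if (v[k] > 0 && v[k + 1L] <= 0) { j <- k; break }
  }
  if (is.na(j))
    stop("no sign change between the maximum and the minimum", call. = FALSE)
  tz <- w$time[j] + (w$time[j + 1L] - w$time[j]) * v[j] / (v[j] - v[j + 1L])
  structure(list(t_vp1 = w$time[i1], t_vp2 = w$time[i2],
                 v_vp1 = v[i1], v_vp2 = v[i2],
                 t_zerocross = tz, i_vp1 = i1, i_vp2 = i2),
            class = "eod_landmarks")
}

#' Detect the pulse bounds by the threshold rules
#'
#' The threshold is `threshold_frac` of the waveform's peak-to-peak
#' amplitude. Start: scanning forward from the first sample, the first index
#' whose next `start_run` samples all exceed the threshold in absolute
#' value. End: scanning forward from the vP2 sample, the first index `j`
#' (with at least `end_window` samples behind it) whose previous
#' `end_window`-point mean voltage exceeds the negative threshold.
#'
#' @param w an `aligned_waveform`.
#' @param cfg a [detection_config()].
#' @param landmarks optional precomputed [find_landmarks()] result.
#' @return list with `t_start`, `t_end` (ms) and indices `i_start`, `i_end`.
#' @export
detect_bounds <- function(w, cfg = detection_config(), landmarks = NULL) {
  stopifnot(inherits(w, "aligned_waveform"))
  lm_ <- landmarks %||% find_landmarks(w)
  v <- w$values
  n <- length(v)
  thr <- cfg$threshold_frac * (max(v) - min(v))
  r <- cfg$start_run
  a <- as.integer(abs(v) > thr)
  cs <- c(0L, cumsum(a))
  runs <- cs[(r + 1L):(n + 1L)] - cs[1:(n - r + 1L)]
  i <- which(runs == r)[1]
  if (is.na(i)) stop("no qualifying start run above threshold", call. = FALSE)
  W <- cfg$end_window
  csv <- c(0, cumsum(v))
  j0 <- max(lm_$i_vp2 + W - 1L, W)
  if (j0 > n) stop("end condition never met before the trace ends", call. = FALSE)
  cand <- j0:n
  tm <- (csv[cand + 1L] - csv[cand + 1L - W]) / W
  j <- cand[which(tm > -thr)[1]]
  if (is.na(j)) stop("end condition never met before the trace ends", call. = FALSE)
  list(t_start = w$time[i], t_end = w$time[j], i_start = i, i_end = j)
}

#' Fit an exponential decay to arbitrary samples
#'
#' Nonlinear least squares of `v = a * exp(-tau * (t - t[1])) + b`.
#' Initialization comes from a log-linear regression of `log(-v)` on `t`
#' assuming `b = 0` (the canonical P2 tail is negative and recovering toward
#' zero). Non-convergence is reported via the `converged` flag, not an error.
#'
#' @param tt sample times (ms); the fit's time origin is `tt[1]`.
#' @param v sample values.
#' @return object of class `decay_fit`: `a`, `b`, `tau` (per ms), `rss`,
#'   `converged`, `n`.
#' @export
fit_exp_decay <- function(tt, v) {
  stop_unless(length(tt) == length(v) && length(v) >= 4,
              "need at least 4 samples to fit the decay")
  x <- tt - tt[1]
  neg <- v < 0
  if (sum(neg) >= 3) {
    ll <- lm(log(-v[neg]) ~ x[neg])
    a0 <- -exp(coef(ll)[[1]])
    tau0 <- max(-coef(ll)[[2]], 1e-3)
  } else {
    a0 <- min(v)
    tau0 <- 1
  }
  # warnOnly: non-convergence is reported through the converged flag
  fit <- suppressWarnings(tryCatch(
    nls(v ~ a * exp(-tau * x) + b,
        start = list(a = a0, tau = tau0, b = 0),
        algorithm = "port",
        lower = c(a = -Inf, tau = 1e-9, b = -Inf),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL))
  if (is.null(fit)) {
    return(structure(list(a = a0, b = 0, tau = tau0,
                          rss = sum((v - a0 * exp(-tau0 * x))^2),
                          converged = FALSE, n = length(v)),
                     class = "decay_fit"))
  }
  cf <- coef(fit)
  structure(list(a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]],
                 rss = sum(resid(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv), n = length(v)),
            class = "decay_fit")
}

#' Fit the P2 recovery time constant of an aligned waveform
#'
#' Fits `v = a * exp(-tau * (t - t_vP2)) + b` to the samples between the P2
#' minimum and the detected pulse end.
#'
#' @param w an `aligned_waveform`.
#' @param landmarks optional [find_landmarks()] result.
#' @param bounds optional [detect_bounds()] result.
#' @param cfg a [detection_config()] (used when bounds must be computed).
#' @return a `decay_fit` (see [fit_exp_decay()]).
#' @export
fit_p2_decay <- function(w, landmarks = NULL, bounds = NULL,
                         cfg = detection_config()) {
  lm_ <- landmarks %||% find_landmarks(w)
  b_ <- bounds %||% detect_bounds(w, cfg, lm_)
  idx <- lm_$i_vp2:b_$i_end
  if (length(idx) < 4)
    stop("fewer than 4 samples between vP2 and the pulse end", call. = FALSE)
  fit_exp_decay(w$time[idx], w$values[idx])
}

#' Extract the standard waveform parameters
#'
#' Computes, on a preprocessed waveform: EOD duration (end - start), P1
#' duration (start to zero crossing), P2 duration (zero crossing to end),
#' P1-P2 delay (vP1 to vP2), vP2/vP1, sP1 (maximum central-difference
#' derivative between the pulse start and vP1, normalized units per ms), the
#' P2 decay constant tau, and the normalized amplitudes vP1 and vP2.
#'
#' @param w an `aligned_waveform`.
#' @param cfg a [detection_config()].
#' @param decay set `FALSE` to skip the (comparatively slow) tau fit.
#' @return a one-row data frame of class `waveform_features`.
#' @examples
#' rec <- simulate_eod_snippet(eod_pulse_params(noise_sd = 0))
#' extract_features(preprocess_recordings(rec))
#' @export
extract_features <- function(w, cfg = detection_config(), decay = TRUE) {
  lm_ <- find_landmarks(w)
  b_ <- detect_bounds(w, cfg, lm_)
  p1 <- lm_$t_zerocross - b_$t_start
  p2 <- b_$t_end - lm_$t_zerocross
  delay <- lm_$t_vp2 - lm_$t_vp1
  stop_unless(delay > 0, "non-positive P1-P2 delay")
  i_lo <- max(b_$i_start, 2L)
  i_hi <- min(lm_$i_vp1, length(w$values) - 1L)
  idx <- i_lo:i_hi
  dv <- (w$values[idx + 1L] - w$values[idx - 1L]) /
    (w$time[idx + 1L] - w$time[idx - 1L])
  tau <- NA_real_
  if (decay) tau <- fit_p2_decay(w, lm_, b_, cfg)$tau
  out <- data.frame(eod_duration = p1 + p2, p1_duration = p1,
                    p2_duration = p2, p1p2_delay = delay,
                    vp2_vp1_ratio = lm_$v_vp2 / lm_$v_vp1,
                    sp1 = max(dv), tau = tau,
                    vp1 = lm_$v_vp1, vp2 = lm_$v_vp2)
  class(out) <- c("waveform_features", "data.frame")
  out
}

#' Per-fish per-day features for a simulated or loaded cohort
#'
#' Averages each fish-day's snippets with [preprocess_recordings()] (features
#' are measured on the averaged waveform, not per snippet) and extracts the
#' waveform parameters.
#'
#' @param cohort an `eod_cohort` (see [simulate_cohort()]) or a flat list of
#'   `eod_recording`s carrying fish/treatment/day metadata.
#' @param cfg a [detection_config()].
#' @param decay pass `FALSE` to skip tau (faster).
#' @return data frame: fish, treatment, day, n_averaged + feature columns.
#' @export
cohort_features <- function(cohort, cfg = detection_config(), decay = TRUE) {
  groups <- if (inherits(cohort, "eod_cohort")) {
    unlist(lapply(names(cohort$recordings), function(f) {
      lapply(cohort$recordings[[f]], function(day_recs) day_recs)
    }), recursive = FALSE)
  } else {
    key <- vapply(cohort, function(r)
      paste(r$metadata$fish, r$metadata$day, sep = "@"), character(1))
    split(cohort, key)
  }
  rows <- lapply(groups, function(recs) {
    md <- recs[[1]]$metadata
    w <- preprocess_recordings(recs, cfg)
    cbind(data.frame(fish = md$fish, treatment = md$treatment, day = md$day,
                     n_averaged = length(recs), stringsAsFactors = FALSE),
          extract_features(w, cfg, decay = decay))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$treatment, out$fish, out$day), , drop = FALSE]
}
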