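# Longitudinal acclimation check and between-treatment inference.

#' Acclimation check by trailing coefficient of variation
#'
#' A fish is deemed acclimated on the first day ending a `window`-day
#' trailing window whose coefficient of variation (sample sd / mean) of EOD
#' duration is below `cv_max`.
#'
#' @param durations day-ordered numeric series of EOD durations.
#' @param window consecutive days required (default 5).
#' @param cv_max CV criterion (default 0.05, i.e. < 5%).
#' @param days optional vector of day labels aligned with `durations`;
#'   `first_day` is reported on this scale (default: 1-based position).
#' @return list with `acclimated` (flag) and `first_day` (day ending the
#'   first qualifying window, or `NA`).
#' @export
acclimation_check <- function(durations, window = 5, cv_max = 0.05,
                              days = NULL) {
  stop_unless(is.numeric(durations) && all(is.finite(durations)),
              "'durations' must be finite numeric")
  stop_unless(length(durations) >= window,
              "need at least %d observations", window)
  days <- days %||% seq_along(durations)
  for (i in window:length(durations)) {
    x <- durations[(i - window + 1L):i]
    m <- mean(x)
    if (m <= 0) stop("nonpositive mean duration within a window", call. = FALSE)
    if (sd(x) / m < cv_max)
      return(list(acclimated = TRUE, first_day = days[i]))
  }
  list(acclimated = FALSE, first_day = NA)
}

# shared sums-of-squares for ANOVA / Tukey
anova_ss <- function(groups) {
  stop_unless(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  for (g in groups)
    stop_unless(is.numeric(g) && length(g) >= 2 && all(is.finite(g)),
                "each group needs >= 2 finite observations")
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  gm <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(k = length(groups), n = n, means = m, ssb = ssb, ssw = ssw,
       df_between = length(groups) - 1L, df_within = sum(n) - length(groups))
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares F test. The degenerate case of zero
#' within-group variance with equal means is defined as F = 0, p = 1 (and
#' F = Inf, p = 0 when the means differ).
#'
#' @param groups list of numeric vectors (k >= 2 groups, each n >= 2).
#' @return object of class `anova_result`: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  s <- anova_ss(groups)
  if (s$ssw <= 0) {
    if (s$ssb <= 0) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (s$ssb / s$df_between) / (s$ssw / s$df_within)
    p <- pf(f, s$df_between, s$df_within, lower.tail = FALSE)
  }
  structure(list(F = f, df_between = s$df_between, df_within = s$df_within,
                 p = p), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

# insert-and-absorb compact letter display
cld_insert_absorb <- function(labels, sig_pairs) {
  sets <- list(labels)
  absorb <- function(sets) {
    sets <- unique(lapply(sets, sort))
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
            length(sets[[i]]) < length(sets[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets[keep]
  }
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group1[r]; b <- sig_pairs$group2[r]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      sets <- absorb(Filter(length, new_sets))
    }
  }
  ord <- order(vapply(sets, function(s) min(match(s, labels)), numeric(1)))
  sets <- sets[ord]
  out <- setNames(rep("", length(labels)), labels)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Tukey-Kramer studentized-range test on all group pairs, with adjusted
#' p-values from the studentized range distribution (`stats::ptukey`) on the
#' within-group degrees of freedom, plus a compact letter display from the
#' standard insert-and-absorb algorithm (groups sharing no letter differ at
#' `alpha`).
#'
#' @param groups named list of numeric vectors (unnamed groups are labelled
#'   `group1`, `group2`, ...).
#' @param alpha family-wise significance level for the letters.
#' @return object of class `tukey_result`: `pairs` (data frame: group1,
#'   group2, diff = mean2 - mean1, se, q, p_adj), `letters`, `means`, `mse`,
#'   `df`, `alpha`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  s <- anova_ss(groups)
  mse <- if (s$df_within > 0) s$ssw / s$df_within else 0
  labs <- names(groups)
  cmb <- utils::combn(s$k, 2)
  pairs <- data.frame(
    group1 = labs[cmb[1, ]], group2 = labs[cmb[2, ]],
    diff = s$means[cmb[2, ]] - s$means[cmb[1, ]],
    se = sqrt(mse / 2 * (1 / s$n[cmb[1, ]] + 1 / s$n[cmb[2, ]])),
    stringsAsFactors = FALSE)
  pairs$q <- ifelse(pairs$se > 0, abs(pairs$diff) / pairs$se,
                    ifelse(pairs$diff == 0, 0, Inf))
  pairs$p_adj <- ifelse(is.finite(pairs$q),
                        ptukey(pairs$q, nmeans = s$k, df = s$df_within,
                               lower.tail = FALSE),
                        0)
  pairs$p_adj[pairs$q == 0] <- 1
  rownames(pairs) <- NULL
  lets <- cld_insert_absorb(labs, pairs[pairs$p_adj < alpha, , drop = FALSE])
  structure(list(pairs = pairs, letters = lets,
                 means = setNames(s$means, labs), mse = mse,
                 df = s$df_within, alpha = alpha),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (df = %d, alpha = %g)\n", x$df, x$alpha))
  print(x$pairs, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = " "), "\n")
  invisible(x)
}

#' Treatment-comparison table for per-fish waveform features
#'
#' For each requested measurement and day label, runs the one-way ANOVA
#' across treatments and, where significant at `alpha`, the Tukey HSD
#' (mirroring the two-stage protocol), and builds a summary table of
#' `mean+/-sd` strings with compact letters.
#'
#' @param features data frame from [cohort_features()] (or the same shape).
#' @param measurements feature columns to test.
#' @param alpha significance level.
#' @return list with `summary` (day x treatment x measurement table of
#'   formatted strings) and `tests` (long data frame of ANOVA and Tukey
#'   results).
#' @export
compare_treatments <- function(features,
                               measurements = c("eod_duration", "p1_duration",
                                                "p2_duration", "vp2_vp1_ratio",
                                                "p1p2_delay", "tau", "sp1",
                                                "vp1", "vp2"),
                               alpha = 0.05) {
  # "day 0" and each treatment's own last recorded day
  last_day <- tapply(features$day, features$treatment, max)
  features$day_label <- ifelse(features$day == 0, "day0",
                               ifelse(features$day ==
                                        last_day[features$treatment],
                                      "last", NA))
  tests <- list()
  srows <- list()
  for (dl in c("day0", "last")) {
    sub <- features[!is.na(features$day_label) & features$day_label == dl, ]
    if (!nrow(sub)) next
    for (m in measurements) {
      g <- split(sub[[m]], sub$treatment)
      g <- g[lengths(g) >= 2]
      if (length(g) < 2) next
      an <- one_way_anova(g)
      lets <- setNames(rep("a", length(g)), names(g))
      tk_pairs <- NULL
      if (an$p < alpha) {
        tk <- tukey_hsd(g, alpha = alpha)
        lets <- tk$letters
        tk_pairs <- tk$pairs
      }
      tests[[length(tests) + 1L]] <- data.frame(
        day = dl, measurement = m, test = "anova", group1 = NA, group2 = NA,
        statistic = an$F, p = an$p, stringsAsFactors = FALSE)
      if (!is.null(tk_pairs)) {
        tests[[length(tests) + 1L]] <- data.frame(
          day = dl, measurement = m, test = "tukey",
          group1 = tk_pairs$group1, group2 = tk_pairs$group2,
          statistic = tk_pairs$q, p = tk_pairs$p_adj, stringsAsFactors = FALSE)
      }
      for (tr in names(g)) {
        srows[[length(srows) + 1L]] <- data.frame(
          day = dl, treatment = tr, measurement = m,
          value = sprintf("%.2f±%.2f^%s", mean(g[[tr]]), sd(g[[tr]]),
                          lets[[tr]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, srows)
  wide <- stats::reshape(long, idvar = c("day", "treatment"),
                         timevar = "measurement", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  list(summary = wide, tests = do.call(rbind, tests))
}
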