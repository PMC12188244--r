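# Independent oracles: deliberately naive, loop-based implementations of the
# stated rules, kept free of the package's vectorized code paths.

# exhaustive per-sample scan implementing the bound-detection rules verbatim
oracle_detect_bounds <- function(w, cfg = detection_config()) {
  v <- w$values
  n <- length(v)
  thr <- cfg$threshold_frac * (max(v) - min(v))
  r <- cfg$start_run
  i_start <- NA_integer_
  for (i in 1:(n - r + 1)) {
    ok <- TRUE
    for (k in 0:(r - 1)) if (!(abs(v[i + k]) > thr)) { ok <- FALSE; break }
    if (ok) { i_start <- i; break }
  }
  i_vp2 <- which.min(v)
  W <- cfg$end_window
  i_end <- NA_integer_
  for (j in max(i_vp2 + W - 1, W):n) {
    if (mean(v[(j - W + 1):j]) > -thr) { i_end <- j; break }
  }
  list(i_start = i_start, i_end = i_end,
       t_start = w$time[i_start], t_end = w$time[i_end])
}

# definition-based Benjamini-Hochberg step-up: adj_(i) over sorted p is the
# minimum over j >= i of p_(j) * n / j, capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in 1:n) {
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# sliding-window CV scan
oracle_first_acclimation_day <- function(x, window = 5, cv_max = 0.05) {
  for (i in window:length(x)) {
    s <- x[(i - window + 1):i]
    if (sd(s) / mean(s) < cv_max) return(i)
  }
  NA
}

# random but valid pulse parameters (adjacent phases, pulse inside snippet)
random_pulse_params <- function(noise_sd = 0) {
  a1 <- runif(1, 0.30, 0.50)
  w1 <- runif(1, 0.10, 0.28)
  w2 <- runif(1, 0.10, 0.28)
  eod_pulse_params(a1 = a1, a2 = 1 - a1, t1 = runif(1, 2.6, 3.4),
                   w1 = w1, w2 = w2, tau = runif(1, 15, 40),
                   noise_sd = noise_sd)
}

# minimal contrast table builder for filter/classify tests
contrast_table <- function(genes, log2fc, fdr, pvalue = fdr) {
  data.frame(gene = genes, log2fc = log2fc, pvalue = pvalue, fdr = fdr,
             stringsAsFactors = FALSE)
}

# calls data frame from call vectors
calls_df <- function(genes, broad, early, late,
                     lfc_broad = 0, lfc_early = 0, lfc_late = 0) {
  data.frame(gene = genes, broad = broad, early = early, late = late,
             lfc_broad = lfc_broad, lfc_early = lfc_early,
             lfc_late = lfc_late, stringsAsFactors = FALSE)
}

# ranked profiles with exactly prescribed directional scores
profiles_from_d <- function(d) {
  tabs <- lapply(colnames(d), function(cn) {
    data.frame(gene = rownames(d), log2fc = sign(d[, cn]) + (d[, cn] == 0),
               pvalue = 10^(-abs(d[, cn])), stringsAsFactors = FALSE)
  })
  names(tabs) <- colnames(d)
  build_profiles(tabs)
}
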