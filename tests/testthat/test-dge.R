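# Normalization, stand-in DE, FDR, significance filter, patterns, summaries.

test_that("TMM factors: identical columns, composition invariance, oracle", {
  set.seed(17)
  counts <- matrix(rnbinom(2000 * 4, mu = 100, size = 5), ncol = 4,
                   dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:4)))
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(tmm_normalize(same)$factors, rep(1, 3))
  # doubling a column (same composition) leaves normalized CPM equal
  dbl <- cbind(counts[, 1], counts[, 1] * 2)
  colnames(dbl) <- c("a", "b")
  nrm <- tmm_normalize(dbl)
  expect_equal(nrm$cpm[, 1], nrm$cpm[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)
  # agreement with the reference implementation on random NB data
  fac <- tmm_normalize(counts)$factors
  ref <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(fac, unname(ref), tolerance = 1e-10)
  # spiked toy: factor matches a direct evaluation of the trimmed weighted
  # mean of M-values computed longhand
  toy <- matrix(50, nrow = 20, ncol = 2, dimnames = list(paste0("g", 1:20),
                                                         c("r", "x")))
  set.seed(3)
  toy[, 2] <- rnbinom(20, mu = 50, size = 50)
  toy[1, 2] <- 5000  # spike
  fac2 <- tmm_normalize(toy)$factors
  n1 <- sum(toy[, 1]); n2 <- sum(toy[, 2])
  m <- log2((toy[, 2] / n2) / (toy[, 1] / n1))
  a <- 0.5 * log2((toy[, 2] / n2) * (toy[, 1] / n1))
  w <- (n2 - toy[, 2]) / (n2 * toy[, 2]) + (n1 - toy[, 1]) / (n1 * toy[, 1])
  n <- length(m)
  keep <- rank(m) >= floor(n * .3) + 1 & rank(m) <= n - floor(n * .3) &
    rank(a) >= floor(n * .05) + 1 & rank(a) <= n - floor(n * .05)
  f_raw <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  # reference column is the first (both get geometric-mean rescaling)
  expect_equal(fac2[2] / fac2[1], f_raw, tolerance = 1e-12)
})

test_that("bh_fdr equals the definition-based oracle and base edge cases", {
  expect_identical(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("simple_de: null behaviour and planted-effect detection", {
  set.seed(41)
  # identical groups: p ~ 1, log2fc ~ 0
  base <- matrix(rnbinom(500 * 8, mu = 200, size = 20), ncol = 8,
                 dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:8)))
  same <- cbind(base[, 1:4], base[, 1:4])
  colnames(same) <- paste0("s", 1:8)
  de0 <- simple_de(same, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(all(de0$pvalue > 0.999))
  expect_true(all(abs(de0$log2fc) < 1e-12))
  # null p-values approximately uniform
  de1 <- simple_de(base, paste0("s", 1:4), paste0("s", 5:8))
  expect_gt(ks.test(de1$pvalue, "punif")$p.value, 0.01)
  # all-zero gene is ns with p = 1
  z <- base
  z[1, ] <- 0L
  dez <- simple_de(z, paste0("s", 1:4), paste0("s", 5:8))
  expect_identical(dez$pvalue[1], 1)
  expect_identical(dez$log2fc[1], 0)
  # a strongly planted gene is recovered through filter_degs
  pl <- data.frame(pattern = "broad", direction = "up", effect = 6)
  sim <- simulate_counts(expr_sim_params(n_genes = 1000, planted = pl,
                                         seed = 77))
  ga <- sim$samples$sample[sim$samples$treatment == "control"]
  gb <- sim$samples$sample[sim$samples$treatment == "T8day"]
  de <- simple_de(sim$counts, ga, gb)
  calls <- filter_degs(de)
  expect_identical(calls$call[calls$gene == sim$truth$gene[1]], "up")
})

test_that("filter_degs applies the boundary-inclusive FC and strict FDR", {
  fc <- c(3.9, 4, 4.12)
  fdrs <- c(1e-9, 0.001, 0.01)
  grid <- expand.grid(fc = fc, fdr = fdrs)
  tab <- contrast_table(sprintf("g%d", 1:nrow(grid)), log2(grid$fc), grid$fdr)
  calls <- filter_degs(tab)
  pred <- ifelse(grid$fdr < 0.001 & grid$fc >= 4, "up", "ns")
  expect_identical(calls$call, pred)
  # down side symmetric, e.g. the FC -4.57 / tiny-FDR case
  tab2 <- contrast_table("g1", -log2(4.57), 1e-5)
  expect_identical(filter_degs(tab2)$call, "down")
  # monotonicity: relaxing thresholds never drops a significant call
  set.seed(4)
  tab3 <- contrast_table(sprintf("g%d", 1:300),
                         rnorm(300, 0, 3), runif(300)^2)
  strict <- filter_degs(tab3, min_fc = 4, max_fdr = 0.001)
  loose <- filter_degs(tab3, min_fc = 2, max_fdr = 0.01)
  was_sig <- strict$call != "ns"
  expect_true(all(loose$call[was_sig] != "ns"))
  expect_identical(loose$call[was_sig], strict$call[was_sig])
})

test_that("pattern classification covers all 27 triples with spec'd labels", {
  lv <- c("up", "down", "ns")
  grid <- expand.grid(broad = lv, early = lv, late = lv,
                      stringsAsFactors = FALSE)
  cl <- classify_patterns(calls_df(sprintf("g%02d", 1:27), grid$broad,
                                   grid$early, grid$late))
  expect_identical(nrow(cl), 27L)
  expect_identical(length(unique(cl$pattern)), 27L)
  lab <- function(b, e, l) cl$pattern[cl$broad == b & cl$early == e &
                                        cl$late == l]
  # broad-only (e.g. a gene significant only in control vs T8day)
  expect_identical(lab("up", "ns", "ns"), "broad_up")
  # early + broad (fast response that persists)
  expect_identical(lab("up", "up", "ns"), "early_up+broad_up")
  # opposite-direction granular changes cancelling broadly
  expect_identical(lab("ns", "down", "up"), "early_down+late_up")
  expect_identical(lab("ns", "ns", "ns"), "ns")
  # conflicts: broad direction contradicted by both granular calls
  expect_true(cl$conflict[cl$broad == "up" & cl$early == "down" &
                            cl$late == "down"])
  expect_identical(sum(cl$conflict), 2L)
  expect_error(classify_patterns(data.frame(broad = "up", early = "ns")),
               "missing contrast")
})

test_that("contrast summary reproduces printed-count arithmetic", {
  mk <- function(n_up, n_dn, n) {
    data.frame(gene = sprintf("g%05d", 1:n),
               call = c(rep("up", n_up), rep("down", n_dn),
                        rep("ns", n - n_up - n_dn)),
               stringsAsFactors = FALSE)
  }
  calls <- list(broad = mk(148, 96, 20887), early = mk(64, 34, 20942),
                late = mk(30, 13, 20401))
  sm <- summarize_contrasts(calls)
  expect_identical(sm$n_deg, c(244L, 98L, 43L) + 0L)
  expect_identical(sm$pct_deg, c(1.17, 0.47, 0.21))
  expect_identical(sm$n_up_long + sm$n_up_short, sm$n_deg)
  expect_identical(summarize_contrasts(list(x = mk(0, 0, 50)))$pct_deg, 0)
  expect_error(summarize_contrasts(list(x = mk(3, 2, 10)),
                                   n_expressed = c(x = 4)), "more DEGs")
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  set.seed(6)
  counts <- matrix(rnbinom(2000 * 5, mu = 50, size = 2), ncol = 5,
                   dimnames = list(NULL, paste0("s", 1:5)))
  counts <- cbind(counts, dup = counts[, 1])
  r <- sample_correlation(counts)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  expect_equal(r["s1", "dup"], 1)
  # independent samples: small mean off-diagonal |r| once the duplicate and
  # the shared mean-abundance structure are removed from consideration
  r5 <- sample_correlation(counts[, 1:5])
  off <- r5[upper.tri(r5)]
  expect_lt(mean(abs(off)), 0.1)
  expect_error(sample_correlation(counts, min_count = 1e9), "no genes")
})
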