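# Synthetic generators: pulse snippets, cohorts, counts, gene-set libraries.

test_that("noise-free snippet has the stated baseline and exact tau truth", {
  p <- eod_pulse_params(noise_sd = 0, offset = 0.3)
  rec <- simulate_eod_snippet(p, seed = 1)
  # pulse centred, tails at baseline
  expect_equal(mean(rec$samples[1:512]), 0.3, tolerance = 1e-12)
  expect_equal(mean(rec$samples[1537:2048]), 0.3, tolerance = 1e-12)
  # default tau carried into the truth exactly
  expect_identical(rec$truth$tau, 31.06)
  expect_equal(rec$truth$v_vp1 - rec$truth$v_vp2, 1)
})

test_that("truth bounds equal a brute-force threshold scan (noise-free)", {
  set.seed(41)
  dtm <- 1000 / 250000
  for (i in 1:25) {
    p <- random_pulse_params(noise_sd = 0)
    rec <- simulate_eod_snippet(p)
    w <- preprocess_recordings(rec)
    sc <- oracle_detect_bounds(w)
    expect_lt(abs(sc$t_start + w$origin_ms - rec$truth$t_start), dtm)
    expect_lt(abs(sc$t_end + w$origin_ms - rec$truth$t_end_rule), dtm)
    expect_lt(abs((sc$t_end - sc$t_start) - rec$truth$duration), 2 * dtm)
  }
})

test_that("pulse not contained in the snippet is an error", {
  expect_error(simulate_eod_snippet(eod_pulse_params(t1 = 8.0)),
               "not contained")
  expect_error(eod_pulse_params(t1 = 3, t2 = 3.2, w1 = 0.2, w2 = 0.2),
               "overlap")
})

test_that("cohort generation is seed-deterministic with day-0 equality", {
  d <- cohort_design(seed = 11, snippets_per_session = 2,
                     days = list(control = c(0, 8), T1day = c(0, 1),
                                 T8day = c(0, 8)))
  a <- simulate_cohort(d)
  b <- simulate_cohort(d)
  expect_identical(a$truth, b$truth)
  expect_identical(a$recordings$control_f01$`0`[[1]]$samples,
                   b$recordings$control_f01$`0`[[1]]$samples)
  # multiplier 1 for everything on day 0 and for control/T1day throughout
  expect_true(all(a$truth$multiplier[a$truth$day == 0] == 1))
  expect_true(all(a$truth$multiplier[a$truth$treatment != "T8day"] == 1))
  expect_true(all(diff(a$truth$multiplier[a$truth$treatment == "T8day" &
                                            a$truth$fish == "T8day_f01"]) >= 0))
})

test_that("default trajectory endpoints land near the published durations", {
  # deterministic endpoints: variability switched off, only the ramp acts
  d <- cohort_design(seed = 5, snippets_per_session = 1,
                     groups = c(control = 1, T8day = 1),
                     days = list(control = c(0, 8), T8day = c(0, 8)),
                     between_fish_cv = 1e-9, day_cv = 1e-9, amp_sd = 1e-9)
  tr <- simulate_cohort(d)$truth
  ctrl_last <- tr$duration[tr$treatment == "control" & tr$day == 8]
  t8_last <- tr$duration[tr$treatment == "T8day" & tr$day == 8]
  expect_equal(ctrl_last, 0.68, tolerance = 0.01)
  # 0.68 x 1.96 = 1.333; the windowed end rule trims the stretched tail a
  # touch further, so the deterministic endpoint sits ~3% under 1.35
  expect_equal(t8_last, 1.35, tolerance = 0.05)
  # and the population mean with default variability stays in the same band
  d2 <- cohort_design(seed = 5, snippets_per_session = 1,
                      groups = c(T8day = 40), days = list(T8day = c(0, 8)))
  tr2 <- simulate_cohort(d2)$truth
  expect_equal(mean(tr2$duration[tr2$day == 8]), 1.35, tolerance = 0.10)
})

test_that("count simulator has NB marginals with the planted structure", {
  # Poisson limit: variance ~ mean at dispersion 0 (many small-mean draws)
  pr <- expr_sim_params(n_genes = 10000, dispersion = 0,
                        group_sizes = c(control = 2, T8day = 2),
                        library_sizes = 5e5, planted = NULL, seed = 3)
  sim <- simulate_counts(pr)
  mu <- rowMeans(sim$counts)
  keep <- mu > 1 & mu < 50
  expect_equal(mean(apply(sim$counts[keep, ], 1, var) /
                      pmax(mu[keep], 1e-9)), 1, tolerance = 0.1)
  # expected column sums equal the library sizes (3 sd band)
  expect_true(all(abs(colSums(sim$counts) - 5e5) < 3 * sqrt(5e5)))

  # doubling one library doubles its expected column sum
  ls <- c(1e6, 2e6, 1e6, 1e6)
  pr2 <- expr_sim_params(n_genes = 5000, group_sizes = c(control = 2, T8day = 2),
                         library_sizes = ls, planted = NULL, seed = 4)
  cs <- colSums(simulate_counts(pr2)$counts)
  expect_equal(unname(cs[2] / cs[1]), 2, tolerance = 0.01)

  # planted pattern -> per-contrast expected log2 fold changes
  pl <- planted_degs(per_class = 2, effect = 4)
  sim3 <- simulate_counts(expr_sim_params(n_genes = 100, planted = pl, seed = 9))
  tru <- sim3$truth
  expect_equal(tru$lfc_broad[tru$pattern == "early" & tru$direction == "up"][1], 4)
  expect_equal(tru$lfc_late[tru$pattern == "early" & tru$direction == "up"][1], 0)
  expect_equal(tru$lfc_early[tru$pattern == "late" & tru$direction == "down"][1], 0)
  expect_equal(tru$lfc_early[tru$pattern == "broad" & tru$direction == "up"][1], 2)
  # errors: inconsistent library sizes
  expect_error(expr_sim_params(group_sizes = c(control = 2, T8day = 2),
                               library_sizes = rep(1e6, 3)),
               "inconsistent")
})

test_that("gene-set simulator respects the universe and records truth", {
  universe <- sprintf("g%05d", 1:500)
  tru <- data.frame(gene = universe[1:60],
                    pattern = rep(c("early", "late", "broad"), each = 20),
                    direction = rep(rep(c("up", "down"), each = 10), 3),
                    effect = rep(c(4, -4), each = 10), stringsAsFactors = FALSE)
  pr <- geneset_sim_params(n_sets = 30, universe = universe,
                           size_range = c(20, 40), n_enriched = 6,
                           extra_sizes = 19L, seed = 2)
  gs <- simulate_geneset_library(pr, tru)
  expect_length(gs$library, 31)  # 30 + the explicit size-19 set
  expect_true(all(unlist(gs$library) %in% universe))
  expect_true(any(lengths(gs$library) == 19))
  expect_identical(sum(gs$truth$enriched), 6L)
  # planted early-up set: positive intended sign in broad and early, 0 late
  r <- gs$truth[gs$truth$enriched & gs$truth$pattern == "early" &
                  gs$truth$direction == "up", ][1, ]
  expect_identical(c(r$sign_broad, r$sign_early, r$sign_late), c(1, 1, 0))
  # determinism
  gs2 <- simulate_geneset_library(pr, tru)
  expect_identical(gs$library, gs2$library)
  # requested size beyond the universe errors
  expect_error(geneset_sim_params(n_sets = 2, universe = universe[1:10],
                                  size_range = c(20, 20)),
               "exceeds")
})
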