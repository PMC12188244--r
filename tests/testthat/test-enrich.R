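# GMT I/O, ranked profiles, set scoring, enrichment and select-set filters.

test_that("GMT round trip, deduplication, and malformed-line errors", {
  lib <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g4"))
  attr(lib, "descriptions") <- c(SET_A = "first", SET_B = "second")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path)
  expect_identical(back[], lib[])
  expect_identical(attr(back, "descriptions"), attr(lib, "descriptions"))
  # duplicated member collapses
  writeLines("S1\tdesc\tg1\tg2\tg1", path)
  expect_identical(read_gmt(path)$S1, c("g1", "g2"))
  # malformed line named by number
  writeLines(c("S1\tdesc\tg1", "broken_line"), path)
  expect_error(read_gmt(path), "line 2")
})

test_that("profiles: scaled ranks, antisymmetry, mid-rank ties", {
  genes <- sprintf("g%02d", 1:6)
  tabs <- list(
    broad = contrast_table(genes, c(2, 1, -1, 0.5, -2, 1),
                           c(1e-6, 1e-3, 1e-2, 0.5, 1e-4, 1e-3)),
    early = contrast_table(genes, rep(1, 6), rep(0.5, 6)),
    late = contrast_table(genes, c(-1, -1, 1, 1, 1, -1),
                          c(0.1, 0.1, 0.2, 0.3, 0.4, 0.5)))
  pr <- build_profiles(tabs)
  # largest positive d gets scaled rank exactly 1
  expect_identical(pr$scaled[which.max(pr$d[, "broad"]), "broad"], 1)
  expect_true(all(pr$scaled > 0 & pr$scaled <= 1))
  # per-column ranks are a permutation (up to mid-rank ties)
  expect_equal(colSums(pr$ranks), rep(sum(1:6), 3), ignore_attr = TRUE)
  # ties in d share the mid-rank: the two identical (0.1, -1) genes
  expect_identical(pr$ranks["g01", "late"], pr$ranks["g02", "late"])
  expect_identical(pr$ranks["g01", "late"], 1.5)
  # flipping every log2fc sign negates the downstream s scores
  flipped <- lapply(tabs, function(tb) { tb$log2fc <- -tb$log2fc; tb })
  lib <- list(S = genes[1:3], FILL = genes)  # minsetsize 2 for the toy
  s1 <- score_gene_sets(pr, lib, minsetsize = 2)
  s2 <- score_gene_sets(build_profiles(flipped), lib, minsetsize = 2)
  expect_equal(s1$s_broad, -s2$s_broad, tolerance = 1e-12)
  expect_equal(s1$s_late, -s2$s_late, tolerance = 1e-12)
  expect_error(build_profiles(list(broad = tabs$broad,
                                   early = contrast_table("zz", 1, 0.5),
                                   late = tabs$late)),
               "empty gene intersection")
})

test_that("set scoring: closed-form s, size filter, |s| bound, S norm", {
  # N = 10 universe, one contrast puts the set at ranks 8, 9, 10:
  # s = 2 * (9 - 5.5) / 10 = 0.7
  d <- cbind(broad = 1:10, early = rep(0, 10), late = rep(0, 10))
  rownames(d) <- sprintf("g%02d", 1:10)
  pr <- profiles_from_d(d)
  sc <- score_gene_sets(pr, list(TOP3 = sprintf("g%02d", 8:10)),
                        minsetsize = 3)
  expect_equal(sc$s_broad, 0.7)
  expect_equal(sc$S, sqrt(0.7^2 + sc$s_early^2 + sc$s_late^2))
  expect_gte(sc$S, max(abs(c(sc$s_broad, sc$s_early, sc$s_late))))
  # a 19-member set is excluded at the default minimum size of 20
  genes20 <- sprintf("g%02d", 1:40)
  d2 <- cbind(broad = seq_len(40), early = seq_len(40), late = seq_len(40))
  rownames(d2) <- genes20
  pr2 <- profiles_from_d(d2)
  sc2 <- score_gene_sets(pr2, list(SMALL = genes20[1:19],
                                   BIG = genes20[1:20]))
  expect_identical(sc2$set, "BIG")
  expect_warning(score_gene_sets(pr2, list(SMALL = genes20[1:19])),
                 "no gene set")
  # |s| <= (N - m)/N, attained by the top-m set: exhaustive at N <= 12
  for (N in c(8, 12)) {
    dN <- cbind(broad = seq_len(N), early = rep(0, N), late = rep(0, N))
    rownames(dN) <- sprintf("h%02d", seq_len(N))
    prN <- profiles_from_d(dN)
    for (m in 2:(N - 1)) {
      combos <- utils::combn(N, m)
      svals <- vapply(seq_len(ncol(combos)), function(j) {
        score_gene_sets(prN, list(S = rownames(dN)[combos[, j]]),
                        minsetsize = m)$s_broad
      }, numeric(1))
      expect_true(all(abs(svals) <= (N - m) / N + 1e-12))
      expect_equal(max(svals), (N - m) / N)   # attained by the top-m set
    }
  }
})

test_that("null sets have centred s and permutation-invariant S", {
  set.seed(12)
  N <- 2000
  d <- cbind(broad = rnorm(N), early = rnorm(N), late = rnorm(N))
  rownames(d) <- sprintf("g%04d", 1:N)
  pr <- profiles_from_d(d)
  svals <- vapply(1:1000, function(i) {
    idx <- sample(N, 50)
    2 * (mean(pr$ranks[idx, "broad"]) - (N + 1) / 2) / N
  }, numeric(1))
  expect_lt(abs(mean(svals)), 0.02)
  # relabeling contrasts permutes s components but leaves S unchanged
  lib <- list(S1 = rownames(d)[1:60])
  sc <- score_gene_sets(pr, lib)
  prp <- profiles_from_d(d[, c("late", "broad", "early")])
  scp <- score_gene_sets(prp, lib)
  expect_equal(sc$S, scp$S, tolerance = 1e-12)
  expect_equal(sc$s_broad, scp$s_broad, tolerance = 1e-12)
})

test_that("enrichment and select filters implement the stated predicates", {
  rows <- data.frame(set = c("a", "b", "c", "d"),
                     s_early = c(0.4, 0.5, 0.3, -0.3),
                     s_late = c(-0.2, 0.5, 0.1, -0.25),
                     S = c(0.3, 0.05, 0.3, 0.4),
                     fdr = c(0.005, 0.005, 0.5, 0.001),
                     stringsAsFactors = FALSE)
  kept <- filter_enriched(rows)
  expect_identical(kept$set, c("a", "d"))   # b fails S, c fails fdr
  sel <- select_gene_sets(rows)
  expect_identical(sel$set, c("a", "c"))    # b and d change by < 0.1
  expect_identical(select_gene_sets(rows, require_sign_change = TRUE)$set, "a")
  # predicate oracle on random rows
  set.seed(77)
  rr <- data.frame(set = sprintf("s%03d", 1:100),
                   s_early = runif(100, -1, 1), s_late = runif(100, -1, 1),
                   S = runif(100, 0, 1.5), fdr = runif(100),
                   stringsAsFactors = FALSE)
  expect_identical(filter_enriched(rr)$set,
                   rr$set[rr$fdr < 0.01 & rr$S > 0.1])
  expect_identical(select_gene_sets(rr, delta = 0.25)$set,
                   rr$set[abs(rr$s_early - rr$s_late) >= 0.25])
})
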