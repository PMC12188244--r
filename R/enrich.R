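# Multi-contrast rank-based gene-set enrichment, GMT I/O, and the
# select-set rule.
#
# The scoring follows the multi-contrast rank approach: each gene gets a
# directional score per contrast, scores are rank-transformed per contrast,
# a set's per-contrast enrichment s is the centred, scaled mean member rank
# (range (-1, 1)), and the higher-dimensional score S is the Euclidean norm
# of the s vector. Significance comes from a two-group MANOVA of the scaled
# ranks (members vs non-members); with two groups Pillai's trace is a
# monotone function of Hotelling's T2, whose F transform is exact, so the
# p-value is computed through T2.

#' Read a GMT gene-set library
#'
#' Tab-separated lines: set name, description, member genes. Duplicate
#' members within a set are dropped.
#'
#' @param path GMT file path.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lib <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 member", i),
           call. = FALSE)
    nm <- f[1]
    if (nm %in% names(lib))
      stop(sprintf("malformed GMT line %d: duplicated set name '%s'", i, nm),
           call. = FALSE)
    lib[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  attr(lib, "descriptions") <- desc
  lib
}

#' Write a gene-set library to GMT
#'
#' @param library named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the
#'   library's `descriptions` attribute, else `"na"`).
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  desc <- descriptions %||% attr(library, "descriptions") %||%
    setNames(rep("na", length(library)), names(library))
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", library[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build multi-contrast ranked profiles from three contrast tables
#'
#' The whole (unfiltered) DE result of each contrast is reduced to a
#' directional score d = sign(log2fc) * (-log10 p) and rank-transformed per
#' contrast (ties mid-ranked); scaled ranks are rank/N in (0, 1].
#'
#' @param tables named list of three `ContrastTable` data frames
#'   (gene, log2fc, pvalue), conventionally named broad/early/late. Genes
#'   are inner-joined across the three.
#' @return object of class `ranked_profiles`: `genes`, `d`, `ranks`,
#'   `scaled`, `n`.
#' @export
build_profiles <- function(tables) {
  stop_unless(is.list(tables) && length(tables) == 3 &&
                !is.null(names(tables)), "need three named contrast tables")
  genes <- Reduce(intersect, lapply(tables, `[[`, "gene"))
  if (length(genes) == 0) stop("empty gene intersection across contrasts",
                               call. = FALSE)
  d <- vapply(tables, function(tb) {
    i <- match(genes, tb$gene)
    p <- pmax(tb$pvalue[i], 1e-300)
    sign(tb$log2fc[i]) * (-log10(p))
  }, numeric(length(genes)))
  rownames(d) <- genes
  ranks <- apply(d, 2, rank)
  structure(list(genes = genes, d = d, ranks = ranks,
                 scaled = ranks / length(genes), n = length(genes)),
            class = "ranked_profiles")
}

# exact two-group MANOVA p (Hotelling T2 <-> Pillai for g = 2); fallback:
# per-column Welch t with Bonferroni min-p when the covariance is singular
manova_p <- function(scaled, members) {
  x1 <- scaled[members, , drop = FALSE]
  x2 <- scaled[!members, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(scaled)
  n <- n1 + n2
  if (n1 < 2 || n2 < 2 || n <= p + 1) return(NA_real_)
  delta <- colMeans(x1) - colMeans(x2)
  sp <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n - 2)
  t2 <- tryCatch(n1 * n2 / n * drop(t(delta) %*% solve(sp, delta)),
                 error = function(e) NA_real_)
  if (is.finite(t2)) {
    f <- (n - p - 1) / (p * (n - 2)) * t2
    return(pf(f, p, n - p - 1, lower.tail = FALSE))
  }
  # singular pooled covariance: univariate fallback
  pv <- vapply(seq_len(p), function(j) {
    v1 <- var(x1[, j]); v2 <- var(x2[, j])
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) return(if (delta[j] == 0) 1 else 0)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    2 * pt(-abs(delta[j] / sqrt(se2)), df)
  }, numeric(1))
  min(1, min(pv) * p)
}

#' Score gene sets across the three contrasts
#'
#' For each set with at least `minsetsize` members in the profile universe:
#' per-contrast enrichment `s = 2 * (mean member rank - (N + 1)/2) / N`
#' (range (-1, 1); attains `(N - m)/N` in magnitude for the top/bottom-m
#' set), the higher-dimensional score `S = sqrt(sum(s^2))`, a MANOVA
#' p-value (members vs background on the scaled ranks) and a BH FDR over
#' the scored sets.
#'
#' @param profiles a [build_profiles()] result.
#' @param library named list of gene-id vectors (sets are intersected with
#'   the profile universe before the size filter; `m` is the intersected
#'   size).
#' @param minsetsize minimum (intersected) set size (default 20).
#' @return data frame: set, m, s_<contrast> per contrast, S, p, fdr. Empty
#'   (with a warning) when no set passes the size filter.
#' @export
score_gene_sets <- function(profiles, library, minsetsize = 20) {
  stopifnot(inherits(profiles, "ranked_profiles"))
  n <- profiles$n
  contrasts <- colnames(profiles$ranks)
  rows <- list()
  for (nm in names(library)) {
    idx <- match(library[[nm]], profiles$genes)
    idx <- idx[!is.na(idx)]
    m <- length(idx)
    if (m < minsetsize) next
    s <- 2 * (colMeans(profiles$ranks[idx, , drop = FALSE]) - (n + 1) / 2) / n
    members <- logical(n)
    members[idx] <- TRUE
    rows[[nm]] <- c(m = m, s, S = sqrt(sum(s^2)),
                    p = manova_p(profiles$scaled, members))
  }
  if (!length(rows)) {
    warning("no gene set passes the minimum size filter")
    out <- data.frame(set = character(), m = integer())
    for (cn in contrasts) out[[paste0("s_", cn)]] <- numeric()
    out$S <- numeric(); out$p <- numeric(); out$fdr <- numeric()
    return(out)
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(set = names(rows), m = as.integer(mat[, "m"]),
                    stringsAsFactors = FALSE)
  for (cn in contrasts) out[[paste0("s_", cn)]] <- mat[, cn]
  out$S <- mat[, "S"]
  out$p <- mat[, "p"]
  # p is NA for degenerate member/background splits; keep them unranked
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Filter enrichment results
#'
#' Keep sets with FDR strictly below `max_fdr` and higher-dimensional score
#' strictly above `min_S`.
#'
#' @param rows a [score_gene_sets()] data frame.
#' @param max_fdr FDR cutoff (default 0.01).
#' @param min_S minimum S (default 0.1).
#' @return filtered rows.
#' @export
filter_enriched <- function(rows, max_fdr = 0.01, min_S = 0.1) {
  keep <- !is.na(rows$fdr) & rows$fdr < max_fdr & rows$S > min_S
  rows[keep, , drop = FALSE]
}

#' Select gene sets with an early-vs-late enrichment change
#'
#' Stand-in for "an important change in enrichment magnitude and direction
#' before and after day 1": keep sets whose early and late enrichment
#' scores differ by at least `delta` (optionally also requiring an actual
#' sign change).
#'
#' @param rows enrichment rows carrying `s_early` and `s_late`.
#' @param delta minimum |s_early - s_late| (default 0.1).
#' @param require_sign_change additionally require
#'   `sign(s_early) != sign(s_late)`.
#' @return the selected rows.
#' @export
select_gene_sets <- function(rows, delta = 0.1, require_sign_change = FALSE) {
  stop_unless(all(c("s_early", "s_late") %in% names(rows)),
              "rows must carry s_early and s_late")
  keep <- abs(rows$s_early - rows$s_late) >= delta
  if (require_sign_change)
    keep <- keep & sign(rows$s_early) != sign(rows$s_late)
  rows[keep, , drop = FALSE]
}
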