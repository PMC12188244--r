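# Count normalization, stand-in differential expression test, significance
# filter, three-contrast pattern classification, and contrast summaries.
#
# The DE test here is deliberately NOT an edgeR replacement: it is a
# documented stand-in (Welch's t on log2 TMM-normalized CPM) so the rest of
# the pipeline can be exercised on synthetic data; externally produced
# per-contrast DE tables are accepted as first-class input everywhere
# downstream.

#' TMM normalization factors (trimmed mean of M-values)
#'
#' Robinson-Oshlack TMM: the reference is the sample whose 75th-percentile
#' count fraction is closest to the mean; each sample's factor is 2 to the
#' precision-weighted mean of gene-wise log ratios (M-values), after trimming
#' 30% of M from each tail and 5% of A (average abundance) from each tail.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes x samples (each sample
#'   with a positive total).
#' @return list with `factors` (per-sample scaling factors), `ref` (reference
#'   sample index), `lib_sizes`, and `cpm` (TMM-normalized counts per
#'   million: `counts / (lib_size * factor) * 1e6`).
#' @export
tmm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  stop_unless(ncol(counts) >= 2, "need at least 2 samples")
  stop_unless(all(counts >= 0), "negative counts")
  lib <- colSums(counts)
  stop_unless(all(lib > 0), "each sample needs a positive total")
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) quantile(counts[, j], 0.75, names = FALSE) / lib[j],
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]
  nr <- lib[ref]
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    yo <- counts[, j]
    no <- lib[j]
    keep <- yo > 0 & yr > 0
    if (!any(keep)) {
      warning("sample ", j, " shares no co-expressed genes with the reference; factor set to 1")
      return(1)
    }
    m <- log2((yo[keep] / no) / (yr[keep] / nr))
    a <- 0.5 * log2((yo[keep] / no) * (yr[keep] / nr))
    w <- (no - yo[keep]) / (no * yo[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    fin <- is.finite(m) & is.finite(a) & is.finite(w)
    m <- m[fin]; a <- a[fin]; w <- w[fin]
    if (!length(m) || max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra_ <- rank(a)
    keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep2)) return(1)
    f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
    if (!is.finite(f)) 1 else 2^f
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  cpm <- sweep(counts, 2, lib * factors, "/") * 1e6
  list(factors = factors, ref = ref, lib_sizes = lib, cpm = cpm)
}

#' Genes considered expressed in a contrast
#'
#' Default rule: nonzero count in at least half of the contrast's samples.
#'
#' @param counts genes x samples count matrix (contrast samples only).
#' @param min_prop minimum fraction of samples with a nonzero count.
#' @return logical vector along the rows of `counts`.
#' @export
expressed_genes <- function(counts, min_prop = 0.5) {
  rowSums(counts > 0) >= min_prop * ncol(counts)
}

#' Stand-in differential expression test for one contrast
#'
#' Welch's t test per gene on log2(TMM-normalized CPM + 0.5), oriented so a
#' positive log2 fold change means higher expression in `group_b` (pass the
#' longer-exposed treatment as `group_b`). Normalization factors are
#' computed on the contrast's samples. Genes with zero counts everywhere get
#' p = 1 and log2fc = 0.
#'
#' @param counts genes x samples count matrix.
#' @param group_a,group_b column names or indices of the two groups
#'   (each >= 2 samples); `group_b` is the longer-exposure treatment.
#' @return `ContrastTable` data frame: gene, log2fc, pvalue, fdr, mean_expr
#'   (mean log2 CPM across the contrast's samples).
#' @export
simple_de <- function(counts, group_a, group_b) {
  counts <- as.matrix(counts)
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  stop_unless(na >= 2 && nb >= 2, "both groups need >= 2 samples")
  x <- log2(tmm_normalize(sub)$cpm + 0.5)
  xa <- x[, seq_len(na), drop = FALSE]
  xb <- x[, na + seq_len(nb), drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  lfc <- mb - ma
  se2 <- va / na + vb / nb
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  t_ <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(t_), df)
  p[se2 == 0] <- ifelse(lfc[se2 == 0] == 0, 1, 0)
  zero <- rowSums(sub) == 0
  p[zero] <- 1
  lfc[zero] <- 0
  out <- data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    log2fc = lfc, pvalue = p, fdr = bh_fdr(p),
                    mean_expr = rowMeans(x), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stop_unless(is.numeric(pvalues) && all(!is.na(pvalues)) &&
                all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  n <- length(pvalues)
  if (n == 0) return(numeric(0))
  o <- order(pvalues)
  adj <- pmin(1, rev(cummin(rev(pvalues[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Significance calls from a contrast table
#'
#' A gene is `up` iff its linear fold change is at least `min_fc` (i.e.
#' log2fc >= log2(min_fc), boundary inclusive) and its FDR is strictly below
#' `max_fdr`; `down` symmetrically; otherwise `ns`.
#'
#' @param table `ContrastTable` data frame (gene, log2fc, fdr).
#' @param min_fc minimum linear fold change (default 4).
#' @param max_fdr FDR cutoff (default 0.001, strict inequality).
#' @return data frame: gene, call (up/down/ns), log2fc, fdr.
#' @export
filter_degs <- function(table, min_fc = 4, max_fdr = 0.001) {
  lt <- log2(min_fc)
  call <- ifelse(table$fdr < max_fdr & table$log2fc >= lt, "up",
                 ifelse(table$fdr < max_fdr & table$log2fc <= -lt, "down",
                        "ns"))
  data.frame(gene = table$gene, call = call, log2fc = table$log2fc,
             fdr = table$fdr, stringsAsFactors = FALSE)
}

#' Combine per-contrast significance calls into one table
#'
#' @param broad,early,late [filter_degs()] outputs for the three contrasts.
#' @return data frame with one row per gene present in all three call
#'   tables: gene, broad, early, late calls (+ per-contrast log2fc columns).
#' @export
combine_calls <- function(broad, early, late) {
  genes <- Reduce(intersect, list(broad$gene, early$gene, late$gene))
  stop_unless(length(genes) > 0, "no shared genes across contrasts")
  ib <- match(genes, broad$gene)
  ie <- match(genes, early$gene)
  il <- match(genes, late$gene)
  data.frame(gene = genes,
             broad = broad$call[ib], early = early$call[ie],
             late = late$call[il],
             lfc_broad = broad$log2fc[ib], lfc_early = early$log2fc[ie],
             lfc_late = late$log2fc[il], stringsAsFactors = FALSE)
}

# pure function of the three calls -> label
pattern_label <- function(broad, early, late) {
  parts <- c(if (early != "ns") paste0("early_", early),
             if (late != "ns") paste0("late_", late),
             if (broad != "ns") paste0("broad_", broad))
  if (is.null(parts)) "ns" else paste(parts, collapse = "+")
}

#' Classify genes by their three-contrast call pattern
#'
#' Deterministic label over the 27 possible (broad, early, late) call
#' triples, e.g. `broad_up` (significant only control vs T8day),
#' `early_up+broad_up`, `early_down+late_up`. The conflict flag marks the
#' biologically contradictory triples where the broad direction opposes both
#' granular directions (never observed in coherent data).
#'
#' @param calls a [combine_calls()] data frame (columns broad, early, late).
#' @return `calls` with `pattern` and `conflict` columns appended.
#' @export
classify_patterns <- function(calls) {
  stop_unless(all(c("broad", "early", "late") %in% names(calls)),
              "missing contrast column (need broad, early, late)")
  calls$pattern <- mapply(pattern_label, calls$broad, calls$early, calls$late,
                          USE.NAMES = FALSE)
  calls$conflict <- (calls$broad == "up" & calls$early == "down" &
                       calls$late == "down") |
                    (calls$broad == "down" & calls$early == "up" &
                       calls$late == "up")
  calls
}

#' Per-contrast DEG summary table
#'
#' The classical three-line summary: genes expressed, genes differentially
#' expressed (with percentage, half-up rounded to two decimals) and the
#' up-regulated count on each side. `n_up_long` counts genes up in the
#' longer-exposure treatment of the contrast (the `up` calls), `n_up_short`
#' the `down` calls.
#'
#' @param calls named list of [filter_degs()] data frames, one per contrast.
#' @param n_expressed named vector of expressed-gene counts per contrast
#'   (default: rows of each call table).
#' @return data frame: contrast, n_expressed, n_deg, pct_deg, n_up_long,
#'   n_up_short.
#' @export
summarize_contrasts <- function(calls, n_expressed = NULL) {
  out <- lapply(names(calls), function(cn) {
    cl <- calls[[cn]]$call
    n_up <- sum(cl == "up")
    n_dn <- sum(cl == "down")
    n_deg <- n_up + n_dn
    ne <- if (is.null(n_expressed)) length(cl) else n_expressed[[cn]]
    stop_unless(n_deg <= ne,
                "contrast %s: more DEGs (%d) than expressed genes (%d)",
                cn, n_deg, ne)
    data.frame(contrast = cn, n_expressed = ne, n_deg = n_deg,
               pct_deg = round_half_up(100 * n_deg / ne, 2),
               n_up_long = n_up, n_up_short = n_dn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample-sample Pearson correlation of log expression
#'
#' Pearson correlation between samples on log2(CPM + 1), restricted to genes
#' exceeding `min_count` reads in at least one sample (the usual exploratory
#' filter).
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param min_count count threshold (strict) for the gene filter.
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(counts, min_count = 10) {
  counts <- as.matrix(counts)
  stop_unless(ncol(counts) >= 2, "need at least 2 samples")
  keep <- apply(counts, 1, max) > min_count
  if (!any(keep)) stop("no genes pass the count filter", call. = FALSE)
  x <- sweep(counts[keep, , drop = FALSE], 2, colSums(counts), "/") * 1e6
  cor(log2(x + 1))
}
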