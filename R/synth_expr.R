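# Negative-binomial count simulator with planted differential expression,
# and a GMT gene-set simulator with planted enrichment.

#' Planted differentially expressed genes
#'
#' Helper building the default `planted` table: `per_class` genes for each
#' (pattern, direction) combination, patterns `early` (effect present from
#' day 1 on), `late` (effect only by day 8) and `broad` (full effect by day 8,
#' half effect at day 1 by default, mirroring the observation that most
#' expression change had materialized by day 1).
#'
#' @param per_class genes per pattern x direction cell.
#' @param effect absolute log2 effect size.
#' @return data frame with columns `pattern`, `direction`, `effect` (signed
#'   log2). Gene ids are assigned by [simulate_counts()].
#' @export
planted_degs <- function(per_class = 10, effect = 4) {
  grid <- expand.grid(pattern = c("early", "late", "broad"),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  out <- grid[rep(seq_len(nrow(grid)), each = per_class), ]
  out$effect <- ifelse(out$direction == "up", effect, -effect)
  rownames(out) <- NULL
  out
}

#' Parameters for the count simulator
#'
#' Defaults emulate the study's bulk electric-organ RNA-seq: ~20,000 genes,
#' samples control n = 6 / T1day n = 7 / T8day n = 7, 20 million reads per
#' library, common NB dispersion 0.05 (typical for tissue-level bulk
#' replicates), gene abundances log-normal on the log2 scale.
#'
#' @param n_genes gene universe size.
#' @param group_sizes named vector of samples per treatment.
#' @param mean_log2,sd_log2 parameters of the baseline log2-abundance draw.
#' @param dispersion common NB dispersion (>= 0; 0 gives the Poisson limit).
#' @param library_sizes per-sample totals (recycled or length `sum(group_sizes)`);
#'   default 2e7 per sample.
#' @param planted data frame of planted effects, see [planted_degs()]; rows
#'   beyond `n_genes` are an error. `NULL` plants nothing.
#' @param broad_early_fraction fraction of the (log2) broad effect already
#'   present at day 1 (default 0.5).
#' @param seed integer seed.
#' @return object of class `expr_sim_params`.
#' @export
expr_sim_params <- function(n_genes = 20000,
                            group_sizes = c(control = 6, T1day = 7, T8day = 7),
                            mean_log2 = 5, sd_log2 = 2, dispersion = 0.05,
                            library_sizes = NULL,
                            planted = planted_degs(),
                            broad_early_fraction = 0.5, seed = 1) {
  stop_unless(is_count(n_genes), "'n_genes' must be a positive integer")
  bad <- setdiff(names(group_sizes), EOD_TREATMENTS)
  stop_unless(length(bad) == 0, "unknown treatment label: %s",
              paste(bad, collapse = ", "))
  stop_unless(all(group_sizes >= 1), "group sizes must be >= 1")
  stop_unless(is_num1(dispersion) && dispersion >= 0,
              "'dispersion' must be >= 0")
  n_samp <- sum(group_sizes)
  if (is.null(library_sizes)) library_sizes <- rep(2e7, n_samp)
  if (length(library_sizes) == 1L) library_sizes <- rep(library_sizes, n_samp)
  stop_unless(length(library_sizes) == n_samp,
              "'library_sizes' inconsistent with group sizes (%d vs %d samples)",
              length(library_sizes), n_samp)
  stop_unless(all(library_sizes > 0), "library sizes must be positive")
  if (!is.null(planted)) {
    stop_unless(all(c("pattern", "direction", "effect") %in% names(planted)),
                "'planted' needs pattern/direction/effect columns")
    stop_unless(nrow(planted) <= n_genes, "more planted genes than genes")
    stop_unless(all(is.finite(planted$effect)), "planted effects must be finite")
    stop_unless(all(planted$pattern %in% c("early", "late", "broad")),
                "planted pattern must be early/late/broad")
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 mean_log2 = mean_log2, sd_log2 = sd_log2,
                 dispersion = dispersion, library_sizes = library_sizes,
                 planted = planted,
                 broad_early_fraction = broad_early_fraction,
                 seed = as.integer(seed)),
            class = "expr_sim_params")
}

# per-treatment log2 effect matrix for the planted table
planted_effect_matrix <- function(planted, broad_early_fraction) {
  e <- matrix(0, nrow(planted), 3,
              dimnames = list(NULL, EOD_TREATMENTS))
  for (i in seq_len(nrow(planted))) {
    eff <- planted$effect[i]
    e[i, ] <- switch(planted$pattern[i],
      early = c(0, eff, eff),
      late  = c(0, 0, eff),
      broad = c(0, eff * broad_early_fraction, eff))
  }
  e
}

#' Simulate an RNA-seq count matrix with planted DE genes
#'
#' Baseline relative abundances are drawn once, per-treatment log2 effects
#' are applied to the planted genes, per-sample expected counts are the
#' library size times the renormalized abundance, and counts are drawn
#' NB(mu, dispersion) (Poisson when dispersion = 0). Expected column sums
#' equal the library sizes exactly.
#'
#' Planted truth per contrast: `early` genes are shifted in both treated
#' groups (so they appear in the broad and early contrasts and cancel in the
#' late one); `late` genes only in T8day (broad + late contrasts); `broad`
#' genes carry the full effect in T8day and `broad_early_fraction` of it in
#' T1day (all three contrasts, at half strength in early/late).
#'
#' @param params an [expr_sim_params()] object.
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (data frame sample/treatment), `truth` (planted table with gene ids and
#'   per-contrast expected log2 fold changes) and `params`.
#' @export
simulate_counts <- function(params = expr_sim_params()) {
  stopifnot(inherits(params, "expr_sim_params"))
  set.seed(params$seed)
  genes <- sprintf("g%05d", seq_len(params$n_genes))
  base <- 2^rnorm(params$n_genes, params$mean_log2, params$sd_log2)
  treatments <- rep(names(params$group_sizes), params$group_sizes)
  samples <- sprintf("%s_s%02d", treatments,
                     unlist(lapply(params$group_sizes, seq_len)))
  mult <- matrix(1, params$n_genes, 3, dimnames = list(NULL, EOD_TREATMENTS))
  truth <- NULL
  if (!is.null(params$planted) && nrow(params$planted) > 0) {
    truth <- params$planted
    truth$gene <- genes[seq_len(nrow(truth))]
    e <- planted_effect_matrix(truth, params$broad_early_fraction)
    mult[seq_len(nrow(truth)), ] <- 2^e
    truth$lfc_broad <- e[, "T8day"] - e[, "control"]
    truth$lfc_early <- e[, "T1day"] - e[, "control"]
    truth$lfc_late  <- e[, "T8day"] - e[, "T1day"]
  }
  counts <- matrix(0L, params$n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- base * mult[, treatments[j]]
    mu <- params$library_sizes[j] * mu / sum(mu)
    counts[, j] <- if (params$dispersion == 0) {
      rpois(params$n_genes, mu)
    } else {
      rnbinom(params$n_genes, mu = mu, size = 1 / params$dispersion)
    }
  }
  list(counts = counts,
       samples = data.frame(sample = samples, treatment = treatments,
                            stringsAsFactors = FALSE),
       truth = truth, params = params)
}

#' Parameters for the gene-set library simulator
#'
#' @param n_sets total number of gene sets.
#' @param universe character vector of gene ids shared with the count matrix.
#' @param size_range inclusive range of random (null) set sizes.
#' @param n_enriched number of planted enriched sets (cycled over the
#'   pattern x direction combinations present in the expression truth).
#' @param enriched_size_range size range for planted sets.
#' @param purity fraction of a planted set drawn from matching planted DE
#'   genes (the rest is random background).
#' @param extra_sizes optional integer vector of additional set sizes to
#'   generate verbatim (e.g. `19` to exercise the minimum-size filter).
#' @param seed integer seed.
#' @return object of class `geneset_sim_params`.
#' @export
geneset_sim_params <- function(n_sets = 200, universe, size_range = c(25, 80),
                               n_enriched = 10,
                               enriched_size_range = c(25, 40),
                               purity = 0.75, extra_sizes = integer(),
                               seed = 1) {
  stop_unless(is_count(n_sets), "'n_sets' must be a positive integer")
  stop_unless(length(universe) >= max(size_range, enriched_size_range,
                                      extra_sizes, 1),
              "requested set size exceeds the gene universe")
  stop_unless(all(size_range >= 1) && all(enriched_size_range >= 1),
              "set sizes must be >= 1")
  stop_unless(is_num1(purity) && purity >= 0 && purity <= 1,
              "'purity' must be in [0, 1]")
  structure(list(n_sets = as.integer(n_sets), universe = universe,
                 size_range = size_range, n_enriched = as.integer(n_enriched),
                 enriched_size_range = enriched_size_range, purity = purity,
                 extra_sizes = as.integer(extra_sizes),
                 seed = as.integer(seed)),
            class = "geneset_sim_params")
}

# expected enrichment sign per contrast for a planted (pattern, direction)
planted_set_signs <- function(pattern, direction) {
  s <- if (direction == "up") 1 else -1
  switch(pattern,
         early = c(broad = s, early = s, late = 0),
         late  = c(broad = s, early = 0, late = s),
         broad = c(broad = s, early = s, late = s))
}

#' Simulate a GMT-writable gene-set library with planted enrichment
#'
#' Null sets are uniform draws from the universe. Planted sets preferentially
#' sample planted DE genes of a designated (pattern, direction), so their
#' rank-based enrichment downstream has a known sign in each contrast.
#'
#' @param params a [geneset_sim_params()] object.
#' @param expr_truth the `truth` component of [simulate_counts()] output
#'   (required when `n_enriched > 0`).
#' @return list with `library` (named list of gene-id vectors), `truth`
#'   (data frame: set, enriched flag, pattern, direction, intended sign per
#'   contrast) and `params`.
#' @export
simulate_geneset_library <- function(params, expr_truth = NULL) {
  stopifnot(inherits(params, "geneset_sim_params"))
  set.seed(params$seed)
  if (params$n_enriched > 0 && is.null(expr_truth))
    stop("planted enriched sets need the expression truth table", call. = FALSE)
  if (!is.null(expr_truth))
    stop_unless(all(expr_truth$gene %in% params$universe),
                "expression truth genes missing from the universe")
  lib <- list()
  rows <- list()
  add_row <- function(set, enriched, pattern, direction) {
    sg <- if (enriched) planted_set_signs(pattern, direction)
          else c(broad = 0, early = 0, late = 0)
    rows[[length(rows) + 1L]] <<- data.frame(
      set = set, enriched = enriched,
      pattern = if (enriched) pattern else NA_character_,
      direction = if (enriched) direction else NA_character_,
      sign_broad = sg[["broad"]], sign_early = sg[["early"]],
      sign_late = sg[["late"]], stringsAsFactors = FALSE)
  }
  combos <- expand.grid(pattern = c("early", "late", "broad"),
                        direction = c("up", "down"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(params$n_enriched)) {
    cm <- combos[(i - 1) %% nrow(combos) + 1, ]
    m <- if (params$enriched_size_range[1] == params$enriched_size_range[2])
      params$enriched_size_range[1]
    else sample(params$enriched_size_range[1]:params$enriched_size_range[2], 1)
    pool <- expr_truth$gene[expr_truth$pattern == cm$pattern &
                            expr_truth$direction == cm$direction]
    n_pl <- min(length(pool), round(params$purity * m))
    members <- sample(pool, n_pl)
    fill <- sample(setdiff(params$universe, members), m - n_pl)
    nm <- sprintf("GS%04d", i)
    lib[[nm]] <- sample(c(members, fill))
    add_row(nm, TRUE, cm$pattern, cm$direction)
  }
  n_null <- params$n_sets - params$n_enriched
  sizes <- c(
    if (n_null > 0) {
      if (params$size_range[1] == params$size_range[2])
        rep(params$size_range[1], n_null)
      else sample(params$size_range[1]:params$size_range[2], n_null,
                  replace = TRUE)
    },
    params$extra_sizes)
  for (k in seq_along(sizes)) {
    nm <- sprintf("GS%04d", params$n_enriched + k)
    lib[[nm]] <- sample(params$universe, sizes[k])
    add_row(nm, FALSE, NA, NA)
  }
  list(library = lib, truth = do.call(rbind, rows), params = params)
}
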