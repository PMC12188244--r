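# End-to-end orchestrator and command-line entry point.
#
# Stage order mirrors the study: waveform -> group statistics; counts ->
# DE -> filter/classify -> enrichment -> select sets -> candidates. A single
# master seed is expanded deterministically per stage (seed + fixed offsets)
# so each stage is independently reproducible.

stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, counts = 202L, genesets = 303L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Run the full pipeline on simulated data
#'
#' Simulates a treatment cohort, extracts per-fish per-day waveform
#' features, runs the day-0 / last-day treatment comparisons, simulates
#' counts with planted DE genes, computes the three oriented contrasts,
#' applies the significance filter and pattern classification, summarizes
#' the contrasts, simulates and scores a gene-set library, applies the
#' enrichment and select-set filters, and derives the candidate table.
#' Every tabular output is written as TSV with a deterministic column
#' order; a JSON manifest records the configuration, seed, per-output row
#' counts and md5 checksums.
#'
#' @param config a [default_config()]-shaped list.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return invisibly, a list with the in-memory stage objects, output paths
#'   and the manifest.
#' @export
run_all <- function(config = default_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  rows <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_file(df, p)
    paths[[name]] <<- p
    rows[[name]] <<- nrow(df)
    p
  }
  det <- detection_config(config$detection$baseline_window,
                          config$detection$threshold_frac,
                          config$detection$start_run,
                          config$detection$end_window)

  log_stage(quiet, "[1/6] simulating EOD cohort (seed %d)",
            stage_seed(config$seed, "cohort"))
  design <- cohort_design(
    snippets_per_session = config$sim$snippets_per_session,
    base = eod_pulse_params(noise_sd = config$sim$noise_sd),
    seed = stage_seed(config$seed, "cohort"))
  cohort <- simulate_cohort(design)

  log_stage(quiet, "[2/6] waveform features (%d fish-days)", nrow(cohort$truth))
  features <- cohort_features(cohort, det)
  emit(features, "features.tsv")
  cmp <- compare_treatments(features, alpha = config$stats$alpha)
  emit(cmp$summary, "stats_summary.tsv")
  emit(cmp$tests, "stats_tests.tsv")

  log_stage(quiet, "[3/6] simulating counts (%d genes)", config$sim$n_genes)
  sim <- simulate_counts(expr_sim_params(
    n_genes = config$sim$n_genes, seed = stage_seed(config$seed, "counts")))
  counts_df <- data.frame(gene = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  emit(counts_df, "counts.tsv")
  emit(sim$samples, "samples.tsv")
  emit(sim$truth, "deg_truth.tsv")

  log_stage(quiet, "[4/6] differential expression (3 contrasts)")
  tables <- list()
  calls <- list()
  n_expressed <- numeric(0)
  for (cn in names(EOD_CONTRASTS)) {
    pair <- EOD_CONTRASTS[[cn]]
    ga <- sim$samples$sample[sim$samples$treatment == pair[1]]
    gb <- sim$samples$sample[sim$samples$treatment == pair[2]]
    sub <- sim$counts[, c(ga, gb), drop = FALSE]
    keep <- expressed_genes(sub, config$dge$min_expr_prop)
    tab <- simple_de(sub[keep, , drop = FALSE], ga, gb)
    tables[[cn]] <- tab
    calls[[cn]] <- filter_degs(tab, config$dge$min_fc, config$dge$max_fdr)
    n_expressed[cn] <- sum(keep)
    emit(tab, sprintf("contrast_%s.tsv", cn))
  }
  combined <- combine_calls(calls$broad, calls$early, calls$late)
  patterns <- classify_patterns(combined)
  emit(patterns, "patterns.tsv")
  emit(summarize_contrasts(calls, n_expressed), "contrast_summary.tsv")
  cor_df <- as.data.frame(sample_correlation(sim$counts))
  emit(cbind(sample = rownames(cor_df), cor_df), "sample_correlation.tsv")

  log_stage(quiet, "[5/6] gene-set enrichment (%d sets)", config$sim$n_sets)
  gs <- simulate_geneset_library(
    geneset_sim_params(n_sets = config$sim$n_sets,
                       universe = rownames(sim$counts),
                       seed = stage_seed(config$seed, "genesets")),
    sim$truth)
  gmt_path <- file.path(out_dir, "library.gmt")
  write_gmt(gs$library, gmt_path)
  paths[["library.gmt"]] <- gmt_path
  rows[["library.gmt"]] <- length(gs$library)
  emit(gs$truth, "geneset_truth.tsv")
  profiles <- build_profiles(tables)
  scored <- score_gene_sets(profiles, gs$library, config$enrich$minsetsize)
  enriched <- filter_enriched(scored, config$enrich$max_fdr,
                              config$enrich$min_S)
  selected <- select_gene_sets(enriched, config$enrich$delta)
  scored$enriched <- scored$set %in% enriched$set
  scored$selected <- scored$set %in% selected$set
  emit(scored, "enrichment.tsv")

  log_stage(quiet, "[6/6] candidate genes (%d select sets)", nrow(selected))
  cand <- derive_candidates(
    selected$set, gs$library, patterns,
    manual_adds = config$candidates$manual_adds,
    policy = exclusion_policy(config$candidates$drop_early_only,
                              config$candidates$blacklist))
  emit(as.data.frame(cand), "candidates.tsv")

  manifest <- list(
    package = "eodkit",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = unclass(config),
    outputs = lapply(setNames(nm = names(paths)), function(nm) {
      list(rows = rows[[nm]], md5 = unname(tools::md5sum(paths[[nm]])))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, features = features, stats = cmp,
                 sim = sim, tables = tables, calls = calls,
                 patterns = patterns, genesets = gs, scored = scored,
                 enriched = enriched, selected = selected,
                 candidates = cand, paths = paths, manifest = manifest))
}

# --- minimal CLI ------------------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts[["_positional"]] <- c(opts[["_positional"]], a)
      i <- i + 1L
    }
  }
  opts
}

cli_config <- function(opts) {
  cfg <- load_config(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts[["min-fc"]])) cfg$dge$min_fc <- as.numeric(opts[["min-fc"]])
  if (!is.null(opts[["max-fdr"]])) cfg$dge$max_fdr <- as.numeric(opts[["max-fdr"]])
  if (!is.null(opts$minsetsize)) cfg$enrich$minsetsize <- as.integer(opts$minsetsize)
  if (!is.null(opts[["min-S"]])) cfg$enrich$min_S <- as.numeric(opts[["min-S"]])
  if (!is.null(opts$delta)) cfg$enrich$delta <- as.numeric(opts$delta)
  if (!is.null(opts$blacklist))
    cfg$candidates$blacklist <- strsplit(opts$blacklist, ",")[[1]]
  validate_config(cfg)
  cfg
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (the full simulated pipeline), `simulate` (write a
#' cohort's recordings as CSV + JSON sidecars), `waveform` (recordings
#' directory -> features TSV). Common options: `--out DIR`, `--config FILE`,
#' `--seed N`, `--quiet`; `run-all` also honours `--min-fc`, `--max-fdr`,
#' `--minsetsize`, `--min-S`, `--delta`, `--blacklist g1,g2`.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly (0 on success).
#' @export
eodkit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: eodkit <run-all|simulate|waveform|stats|dge|enrich|candidates> [--out DIR] [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  out <- opts$out %||% "."
  quiet <- isTRUE(opts$quiet)
  cfg <- cli_config(opts)
  switch(cmd,
    "run-all" = {
      run_all(cfg, out, quiet = quiet)
    },
    "simulate" = {
      design <- cohort_design(
        snippets_per_session = cfg$sim$snippets_per_session,
        base = eod_pulse_params(noise_sd = cfg$sim$noise_sd),
        seed = stage_seed(cfg$seed, "cohort"))
      cohort <- simulate_cohort(design)
      write_recordings(cohort, out)
      write_tsv_file(cohort$truth, file.path(out, "cohort_truth.tsv"))
      log_stage(quiet, "wrote %d fish-days of recordings to %s",
                nrow(cohort$truth), out)
    },
    "waveform" = {
      recs <- read_recordings(opts[["in"]] %||% ".")
      det <- detection_config(cfg$detection$baseline_window,
                              cfg$detection$threshold_frac,
                              cfg$detection$start_run,
                              cfg$detection$end_window)
      feats <- cohort_features(recs, det)
      write_tsv_file(feats, out)
      log_stage(quiet, "wrote %d feature rows to %s", nrow(feats), out)
    },
    "stats" = {
      feats <- read_tsv_file(opts$features)
      cmp <- compare_treatments(feats, alpha = cfg$stats$alpha)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_tsv_file(cmp$summary, file.path(out, "stats_summary.tsv"))
      write_tsv_file(cmp$tests, file.path(out, "stats_tests.tsv"))
    },
    "dge" = {
      cdf <- read_tsv_file(opts$counts)
      counts <- as.matrix(cdf[, -1, drop = FALSE])
      rownames(counts) <- cdf[[1]]
      samples <- read_tsv_file(opts$samples)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      calls <- list()
      n_expressed <- numeric(0)
      for (cn in names(EOD_CONTRASTS)) {
        pair <- EOD_CONTRASTS[[cn]]
        ga <- samples$sample[samples$treatment == pair[1]]
        gb <- samples$sample[samples$treatment == pair[2]]
        sub <- counts[, c(ga, gb), drop = FALSE]
        keep <- expressed_genes(sub, cfg$dge$min_expr_prop)
        tab <- simple_de(sub[keep, , drop = FALSE], ga, gb)
        calls[[cn]] <- filter_degs(tab, cfg$dge$min_fc, cfg$dge$max_fdr)
        n_expressed[cn] <- sum(keep)
        write_tsv_file(tab, file.path(out, sprintf("contrast_%s.tsv", cn)))
      }
      patt <- classify_patterns(combine_calls(calls$broad, calls$early,
                                              calls$late))
      write_tsv_file(patt, file.path(out, "patterns.tsv"))
      write_tsv_file(summarize_contrasts(calls, n_expressed),
                     file.path(out, "contrast_summary.tsv"))
    },
    "enrich" = {
      lib <- read_gmt(opts$gmt)
      tdir <- opts$tables %||% "."
      tables <- lapply(setNames(nm = names(EOD_CONTRASTS)), function(cn)
        read_tsv_file(file.path(tdir, sprintf("contrast_%s.tsv", cn))))
      scored <- score_gene_sets(build_profiles(tables), lib,
                                cfg$enrich$minsetsize)
      enr <- filter_enriched(scored, cfg$enrich$max_fdr, cfg$enrich$min_S)
      sel <- select_gene_sets(enr, cfg$enrich$delta)
      scored$enriched <- scored$set %in% enr$set
      scored$selected <- scored$set %in% sel$set
      write_tsv_file(scored, out)
    },
    "candidates" = {
      scored <- read_tsv_file(opts$enrichment)
      lib <- read_gmt(opts$gmt)
      patt <- read_tsv_file(opts$patterns)
      cand <- derive_candidates(
        scored$set[as.logical(scored$selected)], lib, patt,
        manual_adds = cfg$candidates$manual_adds,
        policy = exclusion_policy(cfg$candidates$drop_early_only,
                                  cfg$candidates$blacklist))
      write_tsv_file(as.data.frame(cand), out)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(0L)
}
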