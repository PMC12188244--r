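# Pipeline configuration: documented defaults, JSON round trip, validation.

#' Default pipeline configuration
#'
#' All stage thresholds with their documented defaults: detection
#' (512-sample baseline window, 0.5% threshold, 3-point start run, 11-point
#' end window), DE filter (minimum fold change 4, FDR < 0.001), enrichment
#' (minimum set size 20, FDR < 0.01, S > 0.1, select delta 0.1), statistics
#' alpha 0.05, candidate policy, simulation sizes and the master seed.
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    detection = list(baseline_window = 512, threshold_frac = 0.005,
                     start_run = 3, end_window = 11),
    dge = list(min_fc = 4, max_fdr = 0.001, min_expr_prop = 0.5),
    enrich = list(minsetsize = 20, max_fdr = 0.01, min_S = 0.1, delta = 0.1),
    stats = list(alpha = 0.05),
    candidates = list(drop_early_only = TRUE, blacklist = character(),
                      manual_adds = character()),
    sim = list(n_genes = 20000, n_sets = 200, snippets_per_session = 10,
               noise_sd = 0.005),
    seed = 1
  ), class = "pipeline_config")
}

config_domains <- list(
  "detection.baseline_window" = function(x) is_count(x),
  "detection.threshold_frac" = function(x) is_num1(x) && x > 0 && x < 0.5,
  "detection.start_run" = function(x) is_count(x),
  "detection.end_window" = function(x) is_count(x),
  "dge.min_fc" = function(x) is_num1(x) && x >= 1,
  "dge.max_fdr" = function(x) is_num1(x) && x > 0 && x <= 1,
  "dge.min_expr_prop" = function(x) is_num1(x) && x >= 0 && x <= 1,
  "enrich.minsetsize" = function(x) is_count(x),
  "enrich.max_fdr" = function(x) is_num1(x) && x > 0 && x <= 1,
  "enrich.min_S" = function(x) is_num1(x) && x >= 0 && x < sqrt(3),
  "enrich.delta" = function(x) is_num1(x) && x >= 0 && x <= 2,
  "stats.alpha" = function(x) is_num1(x) && x > 0 && x < 1,
  "sim.n_genes" = function(x) is_count(x),
  "sim.n_sets" = function(x) is_count(x),
  "sim.snippets_per_session" = function(x) is_count(x),
  "sim.noise_sd" = function(x) is_num1(x) && x >= 0,
  "seed" = function(x) is_num1(x) && x == round(x)
)

#' Validate a pipeline configuration
#'
#' @param config nested configuration list.
#' @return the config, invisibly; errors name the offending key.
#' @export
validate_config <- function(config) {
  for (key in names(config_domains)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- config
    for (p in parts) val <- val[[p]]
    if (is.null(val)) next
    if (!isTRUE(config_domains[[key]](val)))
      stop(sprintf("config key '%s' out of domain (value: %s)", key,
                   paste(format(val), collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

merge_defaults <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      user[[nm]] <- merge_defaults(user[[nm]], defaults[[nm]])
    }
  }
  user
}

#' Load a pipeline configuration from JSON
#'
#' Missing keys take the documented defaults; unknown keys are kept; every
#' known key is validated against its domain. `NULL`, a missing file path,
#' or an empty file give the full default configuration.
#'
#' @param path JSON file path or `NULL`.
#' @return `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path) && file.exists(path) &&
      nzchar(paste(readLines(path, warn = FALSE), collapse = ""))) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg2 <- merge_defaults(user, unclass(default_config()))
    # JSON has no empty character vector: [] round-trips as list()
    for (f in c("blacklist", "manual_adds"))
      cfg2$candidates[[f]] <- as.character(unlist(cfg2$candidates[[f]]))
    cfg <- structure(cfg2, class = "pipeline_config")
  }
  validate_config(cfg)
  cfg
}

#' Save a pipeline configuration to JSON
#'
#' @param config a configuration list.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
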