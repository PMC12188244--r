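# Recording file I/O: one CSV per snippet (single voltage column) with a
# JSON sidecar carrying the sampling metadata.

#' Write cohort recordings to disk
#'
#' Each snippet becomes `<fish>_day<dd>_s<ss>.csv` (header `voltage`, one
#' sample per line) plus a `.json` sidecar with `sample_rate`, `npts`,
#' `fish`, `treatment`, `day`, `snippet`.
#'
#' @param cohort an `eod_cohort` or flat list of `eod_recording`s.
#' @param dir output directory (created if needed).
#' @return invisibly, the CSV paths written.
#' @export
write_recordings <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- if (inherits(cohort, "eod_cohort"))
    unlist(unlist(cohort$recordings, recursive = FALSE), recursive = FALSE)
  else cohort
  paths <- character(length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    md <- r$metadata
    stem <- sprintf("%s_day%02d_s%02d", md$fish %||% sprintf("rec%04d", i),
                    md$day %||% 0L, md$snippet %||% 1L)
    csv <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(data.frame(voltage = r$samples), csv, row.names = FALSE)
    jsonlite::write_json(
      list(sample_rate = 1 / r$dt, npts = length(r$samples),
           fish = md$fish, treatment = md$treatment, day = md$day,
           snippet = md$snippet),
      file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
    paths[i] <- csv
  }
  invisible(paths)
}

#' Read recordings written by [write_recordings()]
#'
#' @param dir directory of CSV + JSON sidecar pairs.
#' @return flat list of `eod_recording`s (sorted by file name).
#' @export
read_recordings <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  stop_unless(length(csvs) > 0, "no recording CSVs found in %s", dir)
  lapply(csvs, function(csv) {
    side <- paste0(tools::file_path_sans_ext(csv), ".json")
    stop_unless(file.exists(side), "missing sidecar for %s", basename(csv))
    md <- jsonlite::read_json(side, simplifyVector = TRUE)
    v <- utils::read.csv(csv)$voltage
    stop_unless(length(v) == md$npts, "sample count disagrees with sidecar npts")
    structure(list(samples = v, dt = 1 / md$sample_rate,
                   metadata = md[setdiff(names(md), c("sample_rate", "npts"))],
                   truth = NULL),
              class = "eod_recording")
  })
}
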