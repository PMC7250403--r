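#' Write a synthetic dataset to a directory
#'
#' Plain-text interchange layout: `neural.csv` and `respiration.csv`
#' (single `value` column each, full-precision), `events.csv`,
#' `trial_windows.csv`, `truth.csv` (per-breath ground truth) and
#' `meta.json` (sampling rate, duration, generator configuration). Values
#' round-trip bit-exactly through [read_dataset()].
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # 17 significant digits guarantee bit-exact double round trips
  writeLines(c("value", sprintf("%.17g", dataset$neural)),
             file.path(dir, "neural.csv"))
  writeLines(c("value", sprintf("%.17g", dataset$respiration$samples)),
             file.path(dir, "respiration.csv"))
  readr::write_csv(dataset$events, file.path(dir, "events.csv"))
  readr::write_csv(dataset$trial_windows,
                   file.path(dir, "trial_windows.csv"))
  readr::write_csv(dataset$truth$breaths, file.path(dir, "truth.csv"))
  jsonlite::write_json(
    list(fs = dataset$fs, duration_s = dataset$duration_s,
         config = unclass(dataset$truth$config)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return A `synth_dataset` equivalent to the one written.
#' @export
read_dataset <- function(dir) {
  need <- c("neural.csv", "respiration.csv", "events.csv",
            "trial_windows.csv", "truth.csv", "meta.json")
  missing_f <- need[!file.exists(file.path(dir, need))]
  if (length(missing_f)) {
    abort(sprintf("Dataset directory %s is missing: %s", dir,
                  paste(missing_f, collapse = ", ")))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  cfg <- meta$config
  cfg$duration_s <- NULL   # stored duration may exceed the packed minimum
  cfg <- do.call(synth_config, cfg[names(cfg) %in%
                                     names(formals(synth_config))])
  fs <- as.numeric(meta$fs)
  # base scan(): exact strtod parsing, bit-faithful double round trip
  rd_trace <- function(f) scan(file.path(dir, f), skip = 1, quiet = TRUE)
  structure(list(
    neural = rd_trace("neural.csv"),
    fs = fs,
    respiration = resp_trace(rd_trace("respiration.csv"), fs),
    events = rd("events.csv"),
    trial_windows = rd("trial_windows.csv"),
    truth = list(config = cfg, breaths = rd("truth.csv")),
    duration_s = as.numeric(meta$duration_s)
  ), class = "synth_dataset")
}

#' Write / read an analysis configuration as YAML
#'
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored `analysis_config` (read).
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[names(raw) %in% names(formals(analysis_config))]
  raw$paths <- as.character(unlist(raw$paths))
  if (!is.null(raw$synth)) raw$synth <- as.list(raw$synth)
  do.call(analysis_config, raw)
}

#' Write all results-bundle tables and maps to a directory
#'
#' Tables go to CSV, time-frequency maps to long-format CSV, and the
#' provenance block to JSON. Every numeric artifact is regenerable
#' bit-identically from the configuration and seeds recorded in
#' `provenance.json`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) readr::write_csv(x, file.path(dir, f))
  wr(tidy(bundle$itpc_combined$anticipatory) |>
       dplyr::mutate(condition = "anticipatory") |>
       dplyr::bind_rows(tidy(bundle$itpc_combined$nonanticipatory) |>
                          dplyr::mutate(condition = "nonanticipatory")),
     "itpc_combined.csv")
  wr(bundle$max_itpc_table, "max_itpc_table.csv")
  wr(bundle$anova, "anova.csv")
  wr(bundle$paired, "paired_tests.csv")
  wr(tidy(bundle$pre_power_zmap), "pre_power_zmap.csv")
  wr(tidy(bundle$post_power_zmap), "post_power_zmap.csv")
  if (!is.null(bundle$surrogate_zmap)) {
    wr(tidy(bundle$surrogate_zmap), "surrogate_zmap.csv")
  }
  wr(bundle$psd, "psd.csv")
  wr(tibble::as_tibble(bundle$dmp), "dmp.csv")
  wr(tidy(bundle$boot_dmp_by_accuracy), "boot_dmp_by_accuracy.csv")
  wr(tidy(bundle$boot_accuracy_by_dmp), "boot_accuracy_by_dmp.csv")
  wr(bundle$median_split$per_subject, "median_split.csv")
  wr(bundle$correlations, "correlations.csv")
  wr(bundle$subject_scalars, "subject_scalars.csv")
  wr(bundle$respiration, "respiration_features.csv")
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
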