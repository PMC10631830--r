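#' Run the full validation pipeline over paired datasets
#'
#' For every dataset, computes the non-invasive PV loop and metrics (method
#' A), the invasive-reference loop and metrics (method B), then the agreement
#' statistics across the seven loop-derived metrics. Deterministic: identical
#' inputs and configuration reproduce identical reports.
#'
#' @param datasets A `pv_cohort` from [make_cohort()], or a list of datasets,
#'   each a list with elements `label`, `vol` ([volume_curve()]), `bp`
#'   ([brachial_bp()]) and `recording` ([catheter_recording()]).
#' @param config A `pv_config`; see [pv_config()].
#' @return A `pv_report` list: `metrics_a`, `metrics_b` (tibbles with one row
#'   per dataset), `pairs` ([pair_metrics()] table), `agreement`
#'   ([compare_all_metrics()] table) and `manifest` (package version and
#'   configuration for provenance).
#' @export
run_pipeline <- function(datasets, config = pv_config()) {
  stopifnot(inherits(config, "pv_config") || is.list(config))
  if (!length(datasets)) abort("`datasets` is empty.")
  elastance <- if (!is.null(config$elastance_path)) {
    read_elastance_csv(config$elastance_path)
  } else {
    default_elastance()
  }
  labels <- purrr::map_chr(seq_along(datasets), function(i) {
    datasets[[i]]$label %||% sprintf("dataset_%02d", i)
  })
  for (i in seq_along(datasets)) {
    for (nm in c("vol", "bp", "recording")) {
      if (is.null(datasets[[i]][[nm]])) {
        abort(sprintf("Dataset `%s`: missing input `%s`.", labels[i], nm),
              class = "pvloopr_input")
      }
    }
  }
  rows <- purrr::map(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    loop_a <- compute_noninvasive_loop(ds$vol, ds$bp,
                                       edp = config$edp_default,
                                       elastance = elastance)
    loop_b <- compute_reference_loop(ds$recording, ds$vol,
                                     cutoff = config$filter_cutoff_hz,
                                     rr_tolerance = config$rr_tolerance)
    list(a = as_tibble(compute_all_metrics(loop_a)),
         b = as_tibble(compute_all_metrics(loop_b)))
  })
  metrics_a <- purrr::list_rbind(purrr::map(rows, "a"))
  metrics_b <- purrr::list_rbind(purrr::map(rows, "b"))
  metrics_a$label <- labels
  metrics_b$label <- labels
  pairs <- pair_metrics(metrics_a, metrics_b, labels = labels)
  structure(
    list(
      metrics_a = metrics_a, metrics_b = metrics_b, pairs = pairs,
      agreement = compare_all_metrics(pairs),
      manifest = list(
        package = "pvloopr",
        version = as.character(utils::packageVersion("pvloopr")),
        config = unclass(config), n_datasets = length(datasets)
      )
    ),
    class = "pv_report"
  )
}

#' Write a pipeline report to a directory
#'
#' Emits `metrics_noninvasive.csv`, `metrics_reference.csv`,
#' `agreement.json` (schema-versioned) and `manifest.json`.
#'
#' @param report A `pv_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pv_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$metrics_a, file.path(dir, "metrics_noninvasive.csv"))
  readr::write_csv(report$metrics_b, file.path(dir, "metrics_reference.csv"))
  jsonlite::write_json(
    list(schema = "pvloopr/agreement/v1", agreement = report$agreement),
    file.path(dir, "agreement.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"
  )
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
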