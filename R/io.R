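#' Read a volume curve from CSV
#'
#' Expects columns `volume_ml` and either `time_s` or `frame` (header
#' required). The heart rate is taken from `heart_rate`, or, when absent, from
#' a JSON sidecar `<path>.json` with a `heart_rate` field.
#'
#' @param path CSV file path.
#' @param heart_rate Heart rate (bpm); overrides any sidecar.
#' @return A [volume_curve()].
#' @export
read_volume_csv <- function(path, heart_rate = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols())
  if (is.null(heart_rate)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      abort("`heart_rate` not given and no JSON sidecar found.")
    }
    heart_rate <- jsonlite::read_json(sidecar)$heart_rate
    if (is.null(heart_rate)) abort("Sidecar lacks a `heart_rate` field.")
  }
  volume_curve(df, heart_rate = as.numeric(heart_rate))
}

#' Write a volume curve to CSV (with JSON sidecar)
#'
#' @param curve A [volume_curve()].
#' @param path Output CSV path; heart rate goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pv_volume_curve"))
  readr::write_csv(as_tibble(curve), path)
  jsonlite::write_json(list(heart_rate = attr(curve, "heart_rate")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a catheter recording from CSV
#'
#' Expects columns `time_s`, `pressure_mmhg` and optionally `volume_cond`.
#' Sample rate and withdrawal offset come from arguments or from a JSON
#' sidecar `<path>.json` (`sample_rate`, `withdrawal_offset`).
#'
#' @param path CSV file path.
#' @param sample_rate Sampling frequency (Hz); overrides the sidecar.
#' @param withdrawal_offset Withdrawal pressure offset (mmHg).
#' @return A [catheter_recording()].
#' @export
read_recording_csv <- function(path, sample_rate = NULL,
                               withdrawal_offset = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols())
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path)
  } else {
    list()
  }
  sample_rate <- sample_rate %||% sidecar$sample_rate %||% 250
  withdrawal_offset <- withdrawal_offset %||% sidecar$withdrawal_offset %||% 0
  catheter_recording(df, sample_rate = as.numeric(sample_rate),
                     withdrawal_offset = as.numeric(withdrawal_offset))
}

#' Write a catheter recording to CSV (with JSON sidecar)
#'
#' @param rec A [catheter_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pv_recording"))
  readr::write_csv(as_tibble(rec), path)
  jsonlite::write_json(
    list(sample_rate = attr(rec, "sample_rate"),
         withdrawal_offset = attr(rec, "withdrawal_offset")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read a PV loop as CSV
#'
#' Columns `t_frac`, `volume_ml`, `pressure_mmhg`; the loop source and heart
#' rate travel in a JSON sidecar.
#'
#' @param loop A `pv_loop`.
#' @param path CSV path.
#' @return `path` ([write_loop_csv()]) or a `pv_loop` ([read_loop_csv()]).
#' @export
write_loop_csv <- function(loop, path) {
  stopifnot(inherits(loop, "pv_loop"))
  readr::write_csv(as_tibble(loop), path)
  jsonlite::write_json(
    list(source = attr(loop, "source"),
         heart_rate = attr(loop, "heart_rate")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_loop_csv
#' @export
read_loop_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path)
  } else {
    list()
  }
  new_pv_loop(df$t_frac, df$volume_ml, df$pressure_mmhg,
              source = meta$source %||% "unknown",
              heart_rate = as.numeric(meta$heart_rate %||% NA_real_))
}

#' Write a metrics row to JSON with explicit units
#'
#' @param metrics A `pv_metrics` row from [compute_all_metrics()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  units <- list(
    sw = "mmHg.mL", pe = "mmHg.mL", pva = "mmHg.mL", espvr = "mmHg/mL",
    ea = "mmHg/mL", ve = "fraction", mep_w = "W",
    mep_mmhg_ml_min = "mmHg.mL/min", epev = "mmHg", emax_pressure = "mmHg",
    emax_volume = "mL", edv = "mL", esv = "mL", sv = "mL", ef = "percent",
    hr = "bpm"
  )
  out <- purrr::map(names(units), function(nm) {
    list(value = metrics[[nm]], unit = units[[nm]])
  })
  names(out) <- names(units)
  jsonlite::write_json(
    list(schema = "pvloopr/metrics/v1",
         source = attr(metrics, "source") %||% "unknown", metrics = out),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults mirror the published computation settings: 7.5 mmHg assumed EDP,
#' 100-point loops, 250-point averaged beats, 10 Hz pressure filter, 20%
#' RR-deviation ectopy threshold and the EDP sensitivity grid
#' 3/7.5/10/16/25/40 mmHg.
#'
#' @param edp_default Assumed EDP (mmHg).
#' @param loop_points Loop sample count (fixed contract: 100).
#' @param avg_beat_points Averaged-beat sample count (fixed contract: 250).
#' @param filter_cutoff_hz Low-pass cutoff (Hz).
#' @param rr_tolerance Relative RR deviation defining ectopy.
#' @param edp_grid EDP sensitivity grid (mmHg, ascending).
#' @param elastance_path Optional CSV path of a user-digitized elastance.
#' @return A `pv_config` list.
#' @export
pv_config <- function(edp_default = 7.5, loop_points = 100,
                      avg_beat_points = 250, filter_cutoff_hz = 10,
                      rr_tolerance = 0.20,
                      edp_grid = c(3, 7.5, 10, 16, 25, 40),
                      elastance_path = NULL) {
  cfg <- list(
    edp_default = edp_default, loop_points = loop_points,
    avg_beat_points = avg_beat_points, filter_cutoff_hz = filter_cutoff_hz,
    rr_tolerance = rr_tolerance, edp_grid = edp_grid,
    elastance_path = elastance_path
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_fields <- c("edp_default", "loop_points", "avg_beat_points",
                  "filter_cutoff_hz", "rr_tolerance")
  for (nm in num_fields) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("Config field `%s` must be a single positive number.", nm),
            class = "pvloopr_config")
    }
  }
  g <- cfg$edp_grid
  if (!is.numeric(g) || length(g) < 1L || any(g <= 0) || is.unsorted(g, strictly = TRUE)) {
    abort("Config `edp_grid` must be positive and strictly ascending.",
          class = "pvloopr_config")
  }
  if (!is.null(cfg$elastance_path) && !is.character(cfg$elastance_path)) {
    abort("Config `elastance_path` must be a file path or NULL.",
          class = "pvloopr_config")
  }
  # keep the optional field present even when NULL (dropped by YAML/modifyList)
  cfg["elastance_path"] <- list(cfg$elastance_path)
  structure(cfg, class = "pv_config")
}

#' Load a YAML configuration, merged with defaults
#'
#' Missing fields take their defaults from [pv_config()]; an absent or empty
#' file yields the full default configuration.
#'
#' @param path YAML file path (may be missing).
#' @return A `pv_config`.
#' @export
load_config <- function(path = NULL) {
  defaults <- unclass(pv_config())
  if (is.null(path) || !file.exists(path)) return(validate_config(defaults))
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(sprintf("Malformed config file: %s", conditionMessage(e)),
          class = "pvloopr_config")
  })
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    abort("Malformed config file: top level must be a mapping.",
          class = "pvloopr_config")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config fields: %s", paste(unknown, collapse = ", ")),
          class = "pvloopr_config")
  }
  merged <- utils::modifyList(defaults, user)
  if (!is.null(merged$edp_grid)) merged$edp_grid <- as.numeric(merged$edp_grid)
  validate_config(merged)
}

#' Write a configuration to YAML
#'
#' @param config A `pv_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pv_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
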