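#' Construct a time-resolved LV volume curve
#'
#' Bundles a single-cycle left-ventricular volume-time curve (one value per
#' reconstructed frame, as exported by cine CMR segmentation tools) with the
#' heart rate at acquisition. The curve is assumed gated so that frame 0 is the
#' R-wave, i.e. end diastole; if the maximal volume occurs elsewhere the
#' constructor warns and records the end-diastolic frame index rather than
#' re-anchoring the cycle.
#'
#' @param data A data frame with a volume column `volume_ml` (mL) and either
#'   `time_s` (seconds from the R-wave, strictly increasing, starting at 0) or
#'   `frame` (0-based frame indices; converted to times as
#'   `frame * cycle_duration / n_frames`).
#' @param heart_rate Heart rate in beats per minute.
#' @return A `pv_volume_curve`: a tibble with columns `time_s`, `volume_ml` and
#'   attributes `heart_rate`, `cycle_duration` (s) and `ed_frame` (row index of
#'   the maximal volume).
#' @examples
#' vol <- make_volume_curve(edv = 324, ef = 32, hr = 72, t_es_frac = 0.40)
#' summarize_volumes(vol)
#' @export
volume_curve <- function(data, heart_rate) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0) {
    abort("`heart_rate` must be a single positive number (beats/min).")
  }
  cycle_duration <- 60 / heart_rate
  if (!"volume_ml" %in% names(data)) abort("`data` must contain `volume_ml`.")
  volumes <- as.numeric(data$volume_ml)
  n <- length(volumes)
  if (n < 8L) abort("A volume curve needs at least 8 frames.")
  if (anyNA(volumes) || any(!is.finite(volumes))) abort("Volumes must be finite.")
  if (any(volumes <= 0)) abort("All volumes must be positive (mL).")

  if ("time_s" %in% names(data)) {
    times <- as.numeric(data$time_s)
  } else if ("frame" %in% names(data)) {
    times <- as.numeric(data$frame) * cycle_duration / n
  } else {
    abort("`data` must contain `time_s` or `frame`.")
  }
  if (any(diff(times) <= 0)) abort("Frame times must be strictly increasing.")
  if (times[1] != 0) abort("Frame times must start at 0 (R-wave).")
  if (times[n] >= cycle_duration) {
    abort("Frame times must lie within [0, cycle_duration).")
  }

  ed_frame <- which.max(volumes)
  if (ed_frame != 1L && ed_frame != n) {
    warn(sprintf(
      "Maximal volume (EDV) at frame %d, not frame 1: curve may not be end-diastolically gated.",
      ed_frame
    ))
  }

  new_tibble(
    tibble(time_s = times, volume_ml = volumes),
    heart_rate = heart_rate,
    cycle_duration = cycle_duration,
    ed_frame = ed_frame,
    class = "pv_volume_curve"
  )
}

#' @export
print.pv_volume_curve <- function(x, ...) {
  cat(sprintf(
    "# LV volume curve: %d frames, HR %.1f bpm (cycle %.3f s)\n",
    nrow(x), attr(x, "heart_rate"), attr(x, "cycle_duration")
  ))
  NextMethod()
}

#' Summarize an LV volume curve
#'
#' Global volumetric indices from a single-cycle volume curve: end-diastolic
#' volume (EDV, the maximum), end-systolic volume (ESV, the minimum), stroke
#' volume (SV = EDV - ESV), ejection fraction (EF = 100 SV/EDV) and the
#' end-systolic time as a cycle fraction (`t_es_frac`, the frame time of the
#' minimal volume divided by the cycle duration; ties broken by the earliest
#' frame).
#'
#' @param curve A [volume_curve()].
#' @return One-row tibble with columns `edv`, `esv`, `sv` (mL), `ef` (percent),
#'   `t_es_frac` (dimensionless) and `hr` (bpm).
#' @export
summarize_volumes <- function(curve) {
  stopifnot(inherits(curve, "pv_volume_curve"))
  v <- curve$volume_ml
  edv <- max(v)
  esv <- min(v)
  if (esv == edv) {
    abort("Degenerate volume curve: EDV equals ESV (stroke volume is zero).",
          class = "pvloopr_degenerate_curve")
  }
  es_idx <- which.min(v) # which.min returns the earliest tie
  tibble(
    edv = edv, esv = esv, sv = edv - esv, ef = 100 * (edv - esv) / edv,
    t_es_frac = curve$time_s[es_idx] / attr(curve, "cycle_duration"),
    hr = attr(curve, "heart_rate")
  )
}

# Periodic cubic-spline evaluation of a cycle-closed curve at arbitrary times.
# Retrospectively gated cine data wrap: V(cycle_duration) = V(0).
periodic_spline_eval <- function(times, values, period, t_out) {
  n <- length(times)
  # replicate one period on each side so the central fit is cycle-closed
  t_ext <- c(times - period, times, times + period)
  v_ext <- rep(values, 3L)
  stats::spline(t_ext, v_ext, xout = t_out %% period, method = "fmm")$y
}

#' Resample a volume curve to a uniform grid
#'
#' Periodic cubic-spline interpolation (the cycle end wraps to the start, as
#' appropriate for a retrospectively gated acquisition) onto `n_points`
#' uniformly spaced times over the cycle.
#'
#' @param curve A [volume_curve()].
#' @param n_points Number of uniform output samples (must be at least the
#'   number of input frames).
#' @return A new `pv_volume_curve` with `n_points` rows.
#' @export
resample_volume_curve <- function(curve, n_points) {
  stopifnot(inherits(curve, "pv_volume_curve"))
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2) {
    abort("`n_points` must be a single number >= 2.")
  }
  n_points <- as.integer(n_points)
  if (n_points < nrow(curve)) {
    abort("`n_points` must be >= the number of input frames.")
  }
  period <- attr(curve, "cycle_duration")
  t_out <- seq(0, period, length.out = n_points + 1L)[seq_len(n_points)]
  v_out <- periodic_spline_eval(curve$time_s, curve$volume_ml, period, t_out)
  volume_curve(
    tibble(time_s = t_out, volume_ml = v_out),
    heart_rate = attr(curve, "heart_rate")
  )
}
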