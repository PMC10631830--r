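#' Construct a normalized elastance curve
#'
#' A normalized time-varying elastance shape \eqn{E_N(x)} on the cycle-fraction
#' grid \eqn{x \in [0, 1]}: near zero at the R-wave, rising to a single peak of
#' exactly 1 during systole, then relaxing back towards baseline. The landmark
#' used for temporal alignment is the middle of the downslope, defined in
#' amplitude: the first cycle fraction after the peak where \eqn{E_N} falls to
#' 0.5 (located by linear interpolation between grid points).
#'
#' @param data Data frame with strictly increasing `t_norm` spanning \[0, 1\]
#'   and non-negative `e_norm`. `e_norm` is renormalized to a maximum of 1.
#' @return A `pv_elastance`: tibble with columns `t_norm`, `e_norm` and
#'   attributes `peak_frac` and `downslope_half_frac`.
#' @seealso [default_elastance()], [warp_to_end_systole()], [scale_amplitude()]
#' @export
elastance_curve <- function(data) {
  if (!is.data.frame(data) || !all(c("t_norm", "e_norm") %in% names(data))) {
    abort("`data` must be a data frame with columns `t_norm` and `e_norm`.")
  }
  t_norm <- as.numeric(data$t_norm)
  e_norm <- as.numeric(data$e_norm)
  if (anyNA(t_norm) || anyNA(e_norm)) abort("Elastance samples must be finite.")
  if (any(diff(t_norm) <= 0)) abort("`t_norm` must be strictly increasing.")
  if (abs(t_norm[1]) > 1e-9 || abs(t_norm[length(t_norm)] - 1) > 1e-9) {
    abort("`t_norm` must span [0, 1].")
  }
  if (any(e_norm < 0)) abort("`e_norm` must be non-negative.")
  e_norm <- e_norm / max(e_norm)
  if (e_norm[1] >= 0.05) {
    abort("Elastance must start near baseline: e_norm(0) < 0.05.")
  }
  pk <- which.max(e_norm)
  tol <- 1e-6
  if (any(diff(e_norm[seq_len(pk)]) < -tol) ||
      any(diff(e_norm[pk:length(e_norm)]) > tol)) {
    abort("Elastance must have a single dominant peak (unimodal shape).")
  }
  half <- downslope_crossing(t_norm, e_norm, pk, level = 0.5)
  if (!(t_norm[pk] > 0 && half < 1)) {
    abort("Peak and downslope landmarks must lie strictly inside (0, 1).")
  }
  new_tibble(
    tibble(t_norm = t_norm, e_norm = e_norm),
    peak_frac = t_norm[pk],
    downslope_half_frac = half,
    class = "pv_elastance"
  )
}

# first crossing of `level` after the peak index, linearly interpolated
downslope_crossing <- function(t_norm, e_norm, pk, level = 0.5) {
  idx <- which(e_norm[pk:length(e_norm)] <= level)[1]
  if (is.na(idx)) abort("Elastance never descends to the half-peak level.")
  i <- pk + idx - 1L
  if (e_norm[i] == level || i == pk) return(t_norm[i])
  frac <- (e_norm[i - 1L] - level) / (e_norm[i - 1L] - e_norm[i])
  t_norm[i - 1L] + frac * (t_norm[i] - t_norm[i - 1L])
}

#' @export
print.pv_elastance <- function(x, ...) {
  cat(sprintf(
    "# Normalized elastance: %d points, peak at %.3f, half-downslope at %.3f\n",
    nrow(x), attr(x, "peak_frac"), attr(x, "downslope_half_frac")
  ))
  NextMethod()
}

#' Packaged default normalized elastance curve
#'
#' Returns the package's normalized human elastance approximation, stored as a
#' CSV data asset so a user-digitized curve can replace it without any code
#' change (see [read_elastance_csv()]). The shape is a double-Hill product
#' \deqn{E_N(x) \propto \frac{(x/\tau_1)^{n_1}}{1 + (x/\tau_1)^{n_1}} \cdot
#'   \frac{1}{1 + (x/\tau_2)^{n_2}}}
#' with \eqn{\tau_1 = 0.269}, \eqn{n_1 = 1.32}, \eqn{\tau_2 = 0.452},
#' \eqn{n_2 = 21.9} on cycle fraction \eqn{x}, renormalized to a peak of 1.
#'
#' @return A `pv_elastance` sampled on 201 uniform points.
#' @export
default_elastance <- function() {
  path <- system.file("extdata", "elastance_default.csv", package = "pvloopr")
  read_elastance_csv(path)
}

#' Read a normalized elastance curve from CSV
#'
#' @param path CSV file with columns `t_norm`, `e_norm` (strictly increasing
#'   `t_norm` spanning \[0, 1\]).
#' @return A `pv_elastance`.
#' @export
read_elastance_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  elastance_curve(df)
}

#' Warp an elastance curve so its downslope midpoint hits end systole
#'
#' The minimal LV volume (the end-systolic frame) is aligned with the middle of
#' the elastance downslope by a piecewise-linear time map sending
#' \[0, downslope_half_frac\] to \[0, t_es_frac\] and
#' \[downslope_half_frac, 1\] to \[t_es_frac, 1\]. The map is a bijection of
#' \[0, 1\] that preserves endpoint values and curve amplitude.
#'
#' @param curve A `pv_elastance`.
#' @param t_es_frac End-systolic time as a cycle fraction, in (0, 1).
#' @return A `pv_elastance` on the same grid with
#'   `downslope_half_frac == t_es_frac` (up to grid resolution).
#' @export
warp_to_end_systole <- function(curve, t_es_frac) {
  stopifnot(inherits(curve, "pv_elastance"))
  if (!is.numeric(t_es_frac) || length(t_es_frac) != 1L ||
      t_es_frac <= 0 || t_es_frac >= 1) {
    abort("`t_es_frac` must be a single number in (0, 1).")
  }
  d <- attr(curve, "downslope_half_frac")
  t <- curve$t_norm
  # inverse map: output time -> native time
  t_native <- ifelse(
    t <= t_es_frac,
    t * d / t_es_frac,
    d + (t - t_es_frac) * (1 - d) / (1 - t_es_frac)
  )
  e_warped <- stats::approx(curve$t_norm, curve$e_norm, xout = t_native,
                            rule = 2)$y
  elastance_curve(tibble(t_norm = t, e_norm = e_warped))
}

#' Scale a (warped) elastance curve to target pressures
#'
#' Produces the absolute elastance \eqn{E(t) = E_0 + k\,\tilde E_N(t)}
#' (mmHg/mL), where \eqn{\tilde E_N} is the normalized curve re-anchored to be
#' exactly 0 at the end-diastolic sample. The offset \eqn{E_0 = EDP/EDV}
#' reproduces the end-diastolic pressure exactly at end diastole, and the
#' amplitude \eqn{k} is solved by bisection so that the peak of
#' \eqn{P(t) = E(t) V(t)} equals the systolic target within 0.05 mmHg; the
#' peak is strictly increasing in \eqn{k}, so bisection converges.
#'
#' @param curve A `pv_elastance`, typically already warped with
#'   [warp_to_end_systole()].
#' @param vol A [volume_curve()]; evaluated on the elastance grid by periodic
#'   spline interpolation.
#' @param lvp_sys Target peak systolic LV pressure (mmHg).
#' @param edp End-diastolic pressure (mmHg); must be below `lvp_sys`.
#' @return A `pv_scaled_elastance`: tibble with `t_frac`, `t_s`, `e_abs`
#'   (mmHg/mL), `volume_ml` and `pressure_mmhg`, plus attributes `e_offset`,
#'   `e_scale` (mmHg/mL) and `ed_index`.
#' @export
scale_amplitude <- function(curve, vol, lvp_sys, edp) {
  stopifnot(inherits(curve, "pv_elastance"), inherits(vol, "pv_volume_curve"))
  if (!is.numeric(lvp_sys) || !is.numeric(edp) || edp <= 0 || lvp_sys <= edp) {
    abort("Pressure ordering violated: need lvp_sys > edp > 0 (mmHg).",
          class = "pvloopr_pressure_ordering")
  }
  period <- attr(vol, "cycle_duration")
  t_frac <- curve$t_norm
  v <- periodic_spline_eval(vol$time_s, vol$volume_ml, period, t_frac * period)
  # anchor at the volume curve's end-diastolic frame time (not the dense-grid
  # argmax, which can land on a spline overshoot next to the true ED sample)
  t_ed <- vol$time_s[attr(vol, "ed_frame")] / period
  ed_index <- which.min(abs(t_frac - t_ed))
  # re-anchor so elastance is exactly zero at end diastole
  e_base <- curve$e_norm - curve$e_norm[ed_index]
  e_offset <- edp / v[ed_index]

  peak_for <- function(scale) max((e_offset + scale * e_base) * v)
  lo <- 0
  hi <- 10 * lvp_sys / min(v)
  if (peak_for(hi) < lvp_sys) {
    abort("Amplitude bracket does not contain the systolic target.",
          class = "pvloopr_numerical")
  }
  # the peak pressure is strictly increasing in the scale, so plain bisection
  # converges; run to bracket exhaustion for a near-exact solve
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (peak_for(mid) < lvp_sys) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(hi, 1)) break
  }
  mid <- (lo + hi) / 2
  if (abs(peak_for(mid) - lvp_sys) > 0.05) {
    abort("Amplitude bisection failed to reach the systolic target within 0.05 mmHg.",
          class = "pvloopr_numerical")
  }
  e_abs <- pmax(e_offset + mid * e_base, 0)
  new_tibble(
    tibble(
      t_frac = t_frac, t_s = t_frac * period, e_abs = e_abs,
      volume_ml = v, pressure_mmhg = e_abs * v
    ),
    e_offset = e_offset, e_scale = mid, ed_index = ed_index,
    class = "pv_scaled_elastance"
  )
}
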