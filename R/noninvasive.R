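#' Brachial blood pressure
#'
#' @param sbp Systolic brachial pressure (mmHg).
#' @param dbp Diastolic brachial pressure (mmHg). Must satisfy
#'   `sbp > dbp > 0`.
#' @return A `pv_brachial_bp` (one-row tibble with `sbp`, `dbp`).
#' @export
brachial_bp <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp) ||
      length(sbp) != 1L || length(dbp) != 1L) {
    abort("`sbp` and `dbp` must be single numbers (mmHg).")
  }
  if (!(sbp > dbp && dbp > 0)) {
    abort("Invalid brachial pressure: need sbp > dbp > 0.",
          class = "pvloopr_invalid_bp")
  }
  new_tibble(tibble(sbp = sbp, dbp = dbp), class = "pv_brachial_bp")
}

#' Estimated peak systolic LV pressure from brachial cuff pressure
#'
#' Applies the standard cuff-to-ventricle approximation
#' \deqn{LVP_{systole} = \tfrac{2}{3} SBP + \tfrac{1}{3} DBP.}
#'
#' @param bp A [brachial_bp()], or the systolic pressure (mmHg) when `dbp` is
#'   also given (the raw formula, without the `sbp > dbp` construction check).
#' @param dbp Optional diastolic pressure (mmHg) when `bp` is numeric.
#' @return Estimated peak systolic LV pressure (mmHg).
#' @examples
#' lvp_systole(brachial_bp(122, 65)) # 103 mmHg
#' @export
lvp_systole <- function(bp, dbp = NULL) {
  if (inherits(bp, "pv_brachial_bp")) {
    return((2 * bp$sbp + bp$dbp) / 3)
  }
  if (is.numeric(bp) && is.numeric(dbp)) {
    return((2 * bp + dbp) / 3)
  }
  abort("`bp` must be a brachial_bp() or numeric sbp with `dbp` supplied.")
}

# internal pv_loop constructor; enforces the loop contract
new_pv_loop <- function(t_frac, volume_ml, pressure_mmhg, source, heart_rate) {
  stopifnot(length(t_frac) == length(volume_ml),
            length(volume_ml) == length(pressure_mmhg))
  if (length(t_frac) != 100L) abort("A PV loop has exactly 100 points.")
  if (any(volume_ml <= 0)) abort("Loop volumes must be positive.")
  if (any(pressure_mmhg < 0)) abort("Loop pressures must be non-negative.")
  emax_index <- which.max(pressure_mmhg / volume_ml)
  new_tibble(
    tibble(t_frac = t_frac, volume_ml = volume_ml,
           pressure_mmhg = pressure_mmhg),
    source = source, heart_rate = heart_rate, emax_index = emax_index,
    class = "pv_loop"
  )
}

#' @export
print.pv_loop <- function(x, ...) {
  cat(sprintf(
    "# PV loop (%s): 100 points, HR %.1f bpm, Emax point #%d\n",
    attr(x, "source"), attr(x, "heart_rate"), attr(x, "emax_index")
  ))
  NextMethod()
}

#' Compute a non-invasive PV loop
#'
#' Assembles the pressure-volume loop from imaging volumes and cuff pressure:
#' the normalized elastance curve is warped in time so its downslope midpoint
#' coincides with the end-systolic (minimal-volume) cycle fraction, scaled in
#' amplitude so that the modelled pressure \eqn{P(t) = E(t) V(t)} (with
#' \eqn{V_0 = 0}) peaks at \eqn{LVP_{systole} = (2 SBP + DBP)/3} and equals the
#' end-diastolic pressure estimate at end diastole, and the resulting
#' pressure-volume trajectory is interpolated linearly in cycle fraction to
#' 100 points.
#'
#' @param vol A [volume_curve()].
#' @param bp A [brachial_bp()].
#' @param edp End-diastolic pressure estimate (mmHg); not measurable from a
#'   cuff, so supplied by the user. Default 7.5 mmHg.
#' @param elastance Normalized elastance shape; defaults to the packaged
#'   curve ([default_elastance()]).
#' @return A `pv_loop` tibble (`t_frac`, `volume_ml`, `pressure_mmhg`; 100
#'   rows) with attributes `source = "noninvasive"`, `heart_rate`,
#'   `emax_index`.
#' @examples
#' vol <- make_volume_curve(edv = 324, ef = 32, hr = 72, t_es_frac = 0.40)
#' loop <- compute_noninvasive_loop(vol, brachial_bp(122, 65))
#' compute_all_metrics(loop)
#' @export
compute_noninvasive_loop <- function(vol, bp, edp = 7.5,
                                     elastance = default_elastance()) {
  stopifnot(inherits(vol, "pv_volume_curve"), inherits(bp, "pv_brachial_bp"),
            inherits(elastance, "pv_elastance"))
  lvp <- lvp_systole(bp)
  if (edp <= 0 || lvp <= edp) {
    abort("Pressure ordering violated: need LVPsystole > EDP > 0.",
          class = "pvloopr_pressure_ordering")
  }
  smry <- summarize_volumes(vol)
  warped <- warp_to_end_systole(elastance, smry$t_es_frac)
  scaled <- scale_amplitude(warped, vol, lvp_sys = lvp, edp = edp)

  t_out <- seq(0, 1, length.out = 101L)[1:100]
  p100 <- stats::approx(scaled$t_frac, scaled$pressure_mmhg, xout = t_out)$y
  v100 <- stats::approx(scaled$t_frac, scaled$volume_ml, xout = t_out)$y
  # affine recalibration about EDP: the dense-grid peak can fall between the
  # 100 output samples, so rescale the excursion to restore the systolic target
  p100 <- edp + (p100 - edp) * (lvp - edp) / (max(p100) - edp)
  p100 <- pmax(p100, 0)
  new_pv_loop(t_out, v100, p100, source = "noninvasive",
              heart_rate = attr(vol, "heart_rate"))
}
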