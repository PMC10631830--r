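#' Stroke work: area enclosed by a PV loop
#'
#' The external work performed by the ventricle over one beat, computed as the
#' absolute polygon (shoelace) area of the pressure-volume vertex sequence.
#' Orientation-independent.
#'
#' @param loop A `pv_loop`, or any data frame with columns `volume_ml` and
#'   `pressure_mmhg` forming a closed loop (last vertex wraps to first).
#' @return Stroke work in mmHg mL.
#' @export
stroke_work <- function(loop) {
  v <- loop$volume_ml
  p <- loop$pressure_mmhg
  if (nrow(unique(cbind(v, p))) < 3L) {
    abort("Degenerate loop: fewer than 3 distinct vertices.",
          class = "pvloopr_degenerate_loop")
  }
  shoelace_area(v, p)
}

shoelace_area <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Slope of the end-systolic pressure-volume relationship
#'
#' The maximal-elastance (Emax) point is the loop sample with the highest
#' pressure-to-volume ratio (the instantaneous elastance with \eqn{V_0 = 0});
#' ESPVR is the slope of the line from the origin through that point. Ties on
#' the maximal ratio are broken by the earliest sample.
#'
#' @param loop A `pv_loop` or data frame with `volume_ml`, `pressure_mmhg`.
#' @return One-row tibble: `espvr` (mmHg/mL), `emax_pressure` (mmHg),
#'   `emax_volume` (mL), `emax_index`.
#' @export
espvr_slope <- function(loop) {
  v <- loop$volume_ml
  p <- loop$pressure_mmhg
  if (any(v <= 0)) abort("All loop volumes must be positive.")
  i <- which.max(p / v) # earliest index on ties
  tibble(espvr = p[i] / v[i], emax_pressure = p[i], emax_volume = v[i],
         emax_index = i)
}

#' Potential energy stored at end systole
#'
#' Simplified triangular potential energy: the area of the triangle with base
#' from \eqn{V_0 = 0} to ESV on the volume axis and height equal to the ESPVR
#' line evaluated at ESV, i.e. \eqn{PE = \tfrac{1}{2} ESV \cdot (ESPVR \cdot
#' ESV)}.
#'
#' @param espvr ESPVR slope (mmHg/mL).
#' @param esv End-systolic volume (mL).
#' @return Potential energy in mmHg mL.
#' @export
potential_energy <- function(espvr, esv) {
  if (espvr < 0 || esv < 0) abort("`espvr` and `esv` must be non-negative.")
  0.5 * esv * (espvr * esv)
}

#' Effective arterial elastance
#'
#' Afterload index: the (absolute) slope of the line from the Emax point to
#' the point (EDV, 0 mmHg), i.e. `emax_pressure / (edv - emax_volume)`.
#'
#' @param loop A `pv_loop` or data frame with `volume_ml`, `pressure_mmhg`.
#' @return Arterial elastance in mmHg/mL.
#' @export
arterial_elastance <- function(loop) {
  em <- espvr_slope(loop)
  edv <- max(loop$volume_ml)
  if (edv <= em$emax_volume) {
    abort("Degenerate geometry: EDV must exceed the Emax-point volume.",
          class = "pvloopr_degenerate_geometry")
  }
  em$emax_pressure / (edv - em$emax_volume)
}

#' Efficiency, power and energy-per-volume indices
#'
#' @param sw Stroke work (mmHg mL), positive.
#' @param pe Potential energy (mmHg mL), non-negative.
#' @param sv Stroke volume (mL), positive.
#' @param hr Heart rate (beats/min), positive.
#' @return One-row tibble: `ve` (ventricular efficiency SW/PVA,
#'   dimensionless), `mep_w` (mean external power SW x HR/60, converted to
#'   watts via 1 mmHg mL = 1.33322e-4 J), `mep_mmhg_ml_min` (the same power in
#'   raw mmHg mL/min), `epev` (energy per ejected volume PVA/SV, mmHg).
#' @export
derived_metrics <- function(sw, pe, sv, hr) {
  if (sw <= 0 || pe < 0) abort("Need sw > 0 and pe >= 0.")
  if (sv <= 0 || hr <= 0) abort("Need sv > 0 and hr > 0.")
  pva <- sw + pe
  tibble(
    ve = sw / pva,
    mep_w = sw * hr / 60 * MMHG_ML_TO_J,
    mep_mmhg_ml_min = sw * hr,
    epev = pva / sv
  )
}

#' All seven loop-derived haemodynamic metrics
#'
#' Composes [stroke_work()], [espvr_slope()], [potential_energy()],
#' [arterial_elastance()] and [derived_metrics()] on one loop. The identity
#' `pva = sw + pe` holds exactly by construction. Applies identically to
#' non-invasive and invasive-reference loops.
#'
#' @param loop A `pv_loop` (or data frame with `volume_ml`, `pressure_mmhg`).
#' @param hr Heart rate in beats/min; defaults to the loop's `heart_rate`
#'   attribute.
#' @return A `pv_metrics` one-row tibble: `sw`, `pe`, `pva` (mmHg mL),
#'   `espvr`, `ea` (mmHg/mL), `ve` (fraction), `mep_w` (W),
#'   `mep_mmhg_ml_min`, `epev` (mmHg), `emax_pressure`, `emax_volume`, `edv`,
#'   `esv`, `sv` (mL), `ef` (percent), `hr` (bpm).
#' @export
compute_all_metrics <- function(loop, hr = attr(loop, "heart_rate")) {
  if (is.null(hr)) abort("`hr` must be supplied when the loop carries none.")
  sw <- stroke_work(loop)
  em <- espvr_slope(loop)
  edv <- max(loop$volume_ml)
  esv <- min(loop$volume_ml)
  sv <- edv - esv
  pe <- potential_energy(em$espvr, esv)
  ea <- arterial_elastance(loop)
  dv <- derived_metrics(sw, pe, sv, hr)
  new_tibble(
    tibble(
      sw = sw, pe = pe, pva = sw + pe, espvr = em$espvr, ea = ea,
      ve = dv$ve, mep_w = dv$mep_w, mep_mmhg_ml_min = dv$mep_mmhg_ml_min,
      epev = dv$epev, emax_pressure = em$emax_pressure,
      emax_volume = em$emax_volume, edv = edv, esv = esv, sv = sv,
      ef = 100 * sv / edv, hr = hr
    ),
    source = attr(loop, "source") %||% "unknown",
    class = "pv_metrics"
  )
}

#' @method glance pv_metrics
#' @export
glance.pv_metrics <- function(x, ...) as_tibble(x)
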