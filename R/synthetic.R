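#' Generate a smooth synthetic LV volume curve
#'
#' Two-phase cycle emulating a clinically plausible volume-time curve:
#' cosine-shaped ejection from EDV down to ESV at `t_es_frac`, a short
#' isovolumic plateau at ESV (so the sampled minimum equals ESV exactly),
#' then biphasic refilling (early rapid filling followed by diastasis and a
#' late atrial kick back to EDV at the next R-wave).
#'
#' @param edv End-diastolic volume (mL).
#' @param ef Ejection fraction (percent), in (0, 100).
#' @param hr Heart rate (beats/min).
#' @param t_es_frac End-systolic time as a cycle fraction, in (0, 0.9).
#' @param n_frames Number of frames (default 25, typical of a retrospectively
#'   gated cine reconstruction).
#' @return A [volume_curve()] with `n_frames` rows, maximum `edv` at frame 0
#'   and minimum `edv * (1 - ef/100)`.
#' @export
make_volume_curve <- function(edv, ef, hr, t_es_frac, n_frames = 25) {
  if (!(ef > 0 && ef < 100)) abort("`ef` must be in (0, 100) percent.")
  if (!(t_es_frac > 0 && t_es_frac < 0.9)) {
    abort("`t_es_frac` must be in (0, 0.9).")
  }
  if (edv <= 0 || hr <= 0) abort("`edv` and `hr` must be positive.")
  if (n_frames < 8L) abort("Need at least 8 frames.")
  esv <- edv * (1 - ef / 100)
  x <- (seq_len(n_frames) - 1L) / n_frames
  plateau <- max(0.04, 1 / n_frames + 1e-9)
  w <- vapply(x, function(xi) {
    if (xi <= t_es_frac) {
      (1 + cos(pi * xi / t_es_frac)) / 2
    } else if (xi <= t_es_frac + plateau) {
      0
    } else {
      u <- (xi - t_es_frac - plateau) / (1 - t_es_frac - plateau)
      early <- 0.5 * (1 - cos(pi * min(u / 0.55, 1)))       # rapid filling
      kick <- if (u < 0.75) 0 else 0.5 * (1 - cos(pi * (u - 0.75) / 0.25))
      0.8 * early + 0.2 * kick
    }
  }, numeric(1))
  volume_curve(
    tibble(time_s = x * 60 / hr, volume_ml = esv + (edv - esv) * w),
    heart_rate = hr
  )
}

#' Ground truth for a synthetic paired CMR + catheter dataset
#'
#' Builds the volume curve, the true scaled elastance, the true pressure beat
#' (sampled at 250 Hz), the true 100-point PV loop and its metrics, all from
#' known parameters, so every downstream pipeline stage can be checked against
#' exact values. In self-consistency mode the true pressures come from the
#' same elastance family the estimator uses; with `shape_mismatch = TRUE` the
#' true shape is perturbed (a power transform of the normalized curve) to
#' emulate model error in real data.
#'
#' @param edv,ef,hr,t_es_frac,n_frames Volume-curve parameters; see
#'   [make_volume_curve()].
#' @param lvp_sys True peak systolic LV pressure (mmHg).
#' @param edp True end-diastolic pressure (mmHg).
#' @param shape_mismatch Perturb the true elastance shape (default FALSE).
#' @return A `pv_ground_truth` list: `vol`, `elastance`, `scaled`
#'   (`pv_scaled_elastance`), `beat` (250 Hz pressure samples over one beat),
#'   `true_peak`, `edp`, `hr`, `true_loop`, `true_metrics`.
#' @export
make_ground_truth <- function(edv = 336, ef = 28, hr = 75, t_es_frac = 0.40,
                              lvp_sys = 107, edp = 7.5, n_frames = 25,
                              shape_mismatch = FALSE) {
  vol <- make_volume_curve(edv, ef, hr, t_es_frac, n_frames = n_frames)
  el <- default_elastance()
  if (shape_mismatch) {
    el <- elastance_curve(tibble(t_norm = el$t_norm, e_norm = el$e_norm^1.15))
  }
  smry <- summarize_volumes(vol)
  warped <- warp_to_end_systole(el, smry$t_es_frac)
  scaled <- scale_amplitude(warped, vol, lvp_sys = lvp_sys, edp = edp)

  period <- 60 / hr
  n_samp <- round(period * 250)
  tb <- (seq_len(n_samp) - 1L) / n_samp
  beat <- tibble(
    time_s = tb * period,
    pressure_mmhg = stats::approx(scaled$t_frac, scaled$pressure_mmhg,
                                  xout = tb)$y
  )
  t100 <- seq(0, 1, length.out = 101L)[1:100]
  true_loop <- new_pv_loop(
    t100,
    stats::approx(scaled$t_frac, scaled$volume_ml, xout = t100)$y,
    stats::approx(scaled$t_frac, scaled$pressure_mmhg, xout = t100)$y,
    source = "truth", heart_rate = hr
  )
  structure(
    list(
      vol = vol, elastance = el, scaled = scaled, beat = beat,
      true_peak = max(scaled$pressure_mmhg), edp = edp, hr = hr,
      true_loop = true_loop, true_metrics = compute_all_metrics(true_loop)
    ),
    class = "pv_ground_truth"
  )
}

#' Simulate a multi-beat catheter pressure recording
#'
#' Concatenates copies of the ground-truth pressure beat at 250 Hz. Each
#' beat's peak is drawn from a Gaussian centred on the true peak with
#' `1.96 * SD = peak_sd_1p96` (beat-to-beat loading variability); i.i.d.
#' Gaussian sample noise is added on top. Ectopic beats are realized as
#' short-coupled beats: the preceding beat's diastole is truncated to 0.6 of
#' the cycle and the ectopic beat's peak is reduced by 30%; subsequent timing
#' is not compensated, so only the ectopic beat's own RR interval deviates.
#'
#' @param truth A `pv_ground_truth` from [make_ground_truth()].
#' @param n_beats Number of beats (>= 3; recordings analysed in practice hold
#'   roughly 19-30).
#' @param peak_sd_1p96 Beat-to-beat peak-pressure variability expressed as
#'   1.96 SD (mmHg); default 6.1.
#' @param noise_sd Additive white measurement noise SD (mmHg); default 1.
#' @param ectopic_beats Number of ectopic beats to inject (must be fewer than
#'   `n_beats / 2`).
#' @param withdrawal_offset Constant pressure offset added to the trace and
#'   recorded in the `withdrawal_offset` attribute (mmHg).
#' @param seed Optional integer seed (local to this call).
#' @return A [catheter_recording()] with attribute `true_onsets` (1-based
#'   sample indices of the true beat onsets).
#' @export
make_catheter_recording <- function(truth, n_beats = 24, peak_sd_1p96 = 6.1,
                                    noise_sd = 1.0, ectopic_beats = 0,
                                    withdrawal_offset = 0, seed = NULL) {
  stopifnot(inherits(truth, "pv_ground_truth"))
  if (n_beats < 3L) abort("`n_beats` must be at least 3.")
  if (ectopic_beats >= n_beats / 2) {
    abort("Too many ectopic beats: would trigger frequent-ectopy rejection.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  pb <- truth$beat$pressure_mmhg
  len <- length(pb)
  pmin_b <- min(pb)
  target_peaks <- truth$true_peak +
    stats::rnorm(n_beats, 0, peak_sd_1p96 / 1.96)

  ect_idx <- integer()
  if (ectopic_beats > 0) {
    pool <- 3:(n_beats - 2L)
    for (k in seq_len(ectopic_beats)) {
      ok <- pool[vapply(pool, function(i) all(abs(i - ect_idx) >= 3L),
                        logical(1))]
      ect_idx <- c(ect_idx, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    ect_idx <- sort(ect_idx)
  }

  segments <- vector("list", n_beats)
  lens <- integer(n_beats)
  for (i in seq_len(n_beats)) {
    f <- (target_peaks[i] - pmin_b) / (truth$true_peak - pmin_b)
    if (i %in% ect_idx) f <- 0.7 * f
    seg <- pmin_b + (pb - pmin_b) * f
    if ((i + 1L) %in% ect_idx) seg <- seg[seq_len(round(0.6 * len))]
    segments[[i]] <- seg
    lens[i] <- length(seg)
  }
  p <- unlist(segments)
  onsets <- c(1L, 1L + cumsum(lens))
  p <- p + stats::rnorm(length(p), 0, noise_sd) + withdrawal_offset

  rec <- catheter_recording(
    tibble(time_s = (seq_along(p) - 1L) / 250, pressure_mmhg = p),
    sample_rate = 250, withdrawal_offset = withdrawal_offset
  )
  attr(rec, "true_onsets") <- onsets
  attr(rec, "ectopic_beats") <- ect_idx
  rec
}

#' Simulate a cohort of paired non-invasive and invasive datasets
#'
#' Draws random haemodynamic states (EDV 150-400 mL, EF 15-45%, HR 60-90 bpm,
#' peak LV pressure 90-140 mmHg, end-systolic fraction 0.35-0.45, 19-30
#' beats), builds each ground truth, a catheter recording, and a brachial
#' pressure obtained by inverting the cuff formula around the true peak plus
#' `brachial_bias_mmhg` (jittered by a factor N(1, 0.2) when non-zero; cuff
#' pressures typically overestimate invasive peaks).
#'
#' @param n_datasets Number of paired datasets (default 8).
#' @param brachial_bias_mmhg Mean brachial-minus-invasive peak pressure bias
#'   (mmHg); default 11. Set 0 for bias-free cuffs.
#' @param peak_sd_1p96,noise_sd Passed to [make_catheter_recording()].
#' @param edp_true True (and assumed) end-diastolic pressure (mmHg).
#' @param seed Optional integer seed (local to this call).
#' @return A `pv_cohort`: list of datasets, each a list with `label`, `vol`,
#'   `bp`, `recording`, `truth`, `n_beats`.
#' @export
make_cohort <- function(n_datasets = 8, brachial_bias_mmHg = 11,
                        peak_sd_1p96 = 6.1, noise_sd = 1.0, edp_true = 7.5,
                        seed = NULL) {
  if (n_datasets < 3L) abort("`n_datasets` must be at least 3.")
  if (!is.null(seed)) withr::local_seed(seed)
  cohort <- purrr::map(seq_len(n_datasets), function(i) {
    truth <- make_ground_truth(
      edv = stats::runif(1, 150, 400),
      ef = stats::runif(1, 15, 45),
      hr = stats::runif(1, 60, 90),
      t_es_frac = stats::runif(1, 0.35, 0.45),
      lvp_sys = stats::runif(1, 90, 140),
      edp = edp_true
    )
    n_beats <- sample(19:30, 1L)
    rec <- make_catheter_recording(
      truth, n_beats = n_beats, peak_sd_1p96 = peak_sd_1p96,
      noise_sd = noise_sd, ectopic_beats = 0
    )
    jitter <- if (brachial_bias_mmHg != 0) stats::rnorm(1, 1, 0.2) else 0
    target <- truth$true_peak + brachial_bias_mmHg * jitter
    pp <- stats::runif(1, 40, 60)
    bp <- brachial_bp(sbp = target + pp / 3, dbp = target + pp / 3 - pp)
    list(label = sprintf("dataset_%02d", i), vol = truth$vol, bp = bp,
         recording = rec, truth = truth, n_beats = n_beats)
  })
  structure(cohort, class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("# Synthetic paired cohort: %d datasets\n", length(x)))
  invisible(x)
}
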