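#' Construct a catheter pressure recording
#'
#' A raw multi-beat LV pressure trace as exported from a conductance-catheter
#' console, nominally ~1 min at 250 Hz, optionally with the conductance-derived
#' volume channel and the pressure offset observed at catheter withdrawal.
#'
#' @param data Data frame with columns `time_s`, `pressure_mmhg` and
#'   optionally `volume_cond` (conductance volume channel, arbitrary units or
#'   mL).
#' @param sample_rate Sampling frequency in Hz (nominal 250).
#' @param withdrawal_offset Pressure recorded at catheter withdrawal (mmHg);
#'   subtracted by [correct_offset()]. Default 0.
#' @return A `pv_recording` tibble with attributes `sample_rate`,
#'   `withdrawal_offset`.
#' @export
catheter_recording <- function(data, sample_rate = 250,
                               withdrawal_offset = 0) {
  if (!is.data.frame(data) ||
      !all(c("time_s", "pressure_mmhg") %in% names(data))) {
    abort("`data` must contain `time_s` and `pressure_mmhg`.")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be positive (Hz).")
  }
  p <- as.numeric(data$pressure_mmhg)
  if (anyNA(p) || any(!is.finite(p))) abort("Pressure samples must be finite.")
  cols <- tibble(time_s = as.numeric(data$time_s), pressure_mmhg = p)
  if ("volume_cond" %in% names(data)) {
    vc <- as.numeric(data$volume_cond)
    if (length(vc) != nrow(cols)) abort("Channel lengths must match.")
    cols$volume_cond <- vc
  }
  new_tibble(cols, sample_rate = sample_rate,
             withdrawal_offset = withdrawal_offset, class = "pv_recording")
}

#' @export
print.pv_recording <- function(x, ...) {
  cat(sprintf(
    "# Catheter recording: %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x), attr(x, "sample_rate"), nrow(x) / attr(x, "sample_rate"),
    if ("volume_cond" %in% names(x)) " + conductance channel" else ""
  ))
  NextMethod()
}

# rebuild a pv_recording with new column content, keeping attributes
rewrap_recording <- function(rec, ...) {
  changes <- list(...)
  cols <- as_tibble(rec)
  for (nm in names(changes)) cols[[nm]] <- changes[[nm]]
  new_tibble(cols, sample_rate = attr(rec, "sample_rate"),
             withdrawal_offset = attr(rec, "withdrawal_offset"),
             class = "pv_recording")
}

#' Zero-phase low-pass filter of the pressure channel
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift, unit DC gain, and at least
#' 20 dB attenuation one octave above the cutoff. Default cutoff 10 Hz.
#'
#' @param rec A [catheter_recording()].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist frequency.
#' @return The recording with a filtered pressure channel.
#' @export
lowpass_filter <- function(rec, cutoff = 10) {
  stopifnot(inherits(rec, "pv_recording"))
  fs <- attr(rec, "sample_rate")
  if (cutoff >= fs / 2) {
    abort("`cutoff` must be below the Nyquist frequency (sample_rate/2).")
  }
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  # pad with edge values to suppress end transients of the two-pass filter
  p <- rec$pressure_mmhg
  npad <- min(length(p) - 1L, as.integer(fs))
  padded <- c(rep(p[1], npad), p, rep(p[length(p)], npad))
  filtered <- signal::filtfilt(bf, padded)
  rewrap_recording(rec, pressure_mmhg = filtered[(npad + 1L):(npad + length(p))])
}

#' Subtract the catheter-withdrawal pressure offset
#'
#' @param rec A [catheter_recording()].
#' @return The recording with `pressure_mmhg` reduced by the
#'   `withdrawal_offset` attribute (which is then zeroed).
#' @export
correct_offset <- function(rec) {
  stopifnot(inherits(rec, "pv_recording"))
  off <- attr(rec, "withdrawal_offset")
  out <- rewrap_recording(rec, pressure_mmhg = rec$pressure_mmhg - off)
  attr(out, "withdrawal_offset") <- 0
  out
}

#' Segment a pressure recording into beats
#'
#' Automatic systolic/diastolic marking: systolic peaks are located first
#' (prominence above the mid-range, refractory spacing of 0.3 s); each beat
#' onset (end diastole) is then placed at the foot of the systolic upstroke
#' by the intersecting-tangent construction standard in pressure-waveform
#' foot detection: the tangent at the maximal-dP/dt sample is extrapolated
#' down to the level of the local pressure minimum immediately preceding the
#' upstroke, and the onset is their crossing. Either landmark alone is
#' biased (the pre-upstroke minimum falls early, a slope threshold late,
#' because LV pressure creeps upward through diastole and the systolic rise
#' starts gently); the tangent crossing recovers end diastole to about one
#' sample at 250 Hz. Each
#' complete beat spans one onset to the next; a trailing segment after the
#' last onset counts as a beat only when it is at least 90% of the median
#' beat length. Onsets can be overridden via `onsets` when manual correction
#' is needed.
#'
#' @param rec A filtered [catheter_recording()] containing at least 2 beats.
#' @param onsets Optional integer vector of sample indices overriding the
#'   automatic onset detection.
#' @return A `pv_beat_set`: tibble with one row per complete beat (`beat`,
#'   `onset`, `end` sample indices, `rr_s` the onset-to-onset interval
#'   preceding each beat - the first beat uses its following interval -
#'   `ectopic`, `retained`) and attribute `sample_rate`.
#' @export
segment_beats <- function(rec, onsets = NULL) {
  stopifnot(inherits(rec, "pv_recording"))
  fs <- attr(rec, "sample_rate")
  p <- rec$pressure_mmhg
  if (is.null(onsets)) {
    rng <- range(p)
    if (diff(rng) < 1e-6) {
      abort("No detectable beats: pressure trace is constant.",
            class = "pvloopr_segmentation")
    }
    peaks <- find_pressure_peaks(p, min_height = rng[1] + 0.5 * diff(rng),
                                 min_dist = as.integer(0.3 * fs))
    if (length(peaks) < 2L) {
      abort("No detectable beats: fewer than 2 systolic peaks found.",
            class = "pvloopr_segmentation")
    }
    dp <- c(0, diff(p))
    bounds <- c(1L, peaks)
    onsets <- vapply(seq_along(peaks), function(k) {
      seg <- bounds[k]:peaks[k]
      up <- seg[which.max(dp[seg])]          # maximal dP/dt of the upstroke
      m <- up                                # local min preceding the upstroke
      while (m > bounds[k] && dp[m] > 0) m <- m - 1L
      foot <- up - (p[up] - p[m]) / dp[up]   # intersecting tangent
      max(m, as.integer(round(foot)))
    }, integer(1))
    onsets <- unique(onsets)
  }
  onsets <- as.integer(onsets)
  if (length(onsets) < 2L) {
    abort("Segmentation needs at least 2 complete beats.",
          class = "pvloopr_segmentation")
  }
  ends <- onsets[-1]
  med_len <- stats::median(diff(onsets))
  tail_len <- length(p) - onsets[length(onsets)] + 1L
  if (tail_len >= 0.9 * med_len) {
    ends <- c(ends, length(p))               # trailing complete beat
  } else {
    onsets <- onsets[-length(onsets)]
  }
  if (length(onsets) < 2L) {
    abort("Segmentation needs at least 2 complete beats.",
          class = "pvloopr_segmentation")
  }
  rr <- (ends - onsets) / fs
  rr_prev <- c(rr[1], rr[-length(rr)])       # preceding interval per beat
  new_tibble(
    tibble(
      beat = seq_along(onsets),
      onset = onsets,
      end = ends,
      rr_s = rr_prev,
      ectopic = FALSE,
      retained = TRUE
    ),
    sample_rate = fs,
    class = "pv_beat_set"
  )
}

# local maxima above min_height, greedily thinned to a refractory distance
find_pressure_peaks <- function(p, min_height, min_dist) {
  n <- length(p)
  cand <- which(p >= min_height)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[p[cand] >= p[cand - 1L] & p[cand] >= p[cand + 1L]]
  if (!length(cand)) return(integer())
  cand <- cand[order(p[cand], decreasing = TRUE)]
  keep <- integer()
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Flag ectopic beats by RR-interval deviation
#'
#' A beat whose RR interval (from the previous onset) deviates from the median
#' RR by more than `rr_tolerance` is flagged ectopic; the ectopic beat and
#' both immediate neighbours are dropped from the retained set, mirroring the
#' manual convention for catheter recordings. If the ectopic fraction exceeds
#' `max_ectopic_fraction` the recording is rejected as frequent ectopy.
#'
#' @param beats A `pv_beat_set` with at least 3 beats.
#' @param rr_tolerance Relative RR deviation that defines ectopy (default
#'   0.20).
#' @param max_ectopic_fraction Ectopic-beat fraction above which the whole
#'   recording is rejected (default 0.25).
#' @return The beat set with `ectopic` and `retained` columns updated.
#' @export
flag_ectopy <- function(beats, rr_tolerance = 0.20,
                        max_ectopic_fraction = 0.25) {
  stopifnot(inherits(beats, "pv_beat_set"))
  n <- nrow(beats)
  if (n < 3L) abort("Ectopy flagging needs at least 3 beats.")
  med <- stats::median(beats$rr_s)
  ect <- abs(beats$rr_s - med) / med > rr_tolerance
  if (mean(ect) > max_ectopic_fraction) {
    abort(sprintf(
      "Frequent ectopy: %d of %d beats ectopic; recording must be excluded.",
      sum(ect), n
    ), class = "pvloopr_frequent_ectopy")
  }
  drop <- ect
  idx <- which(ect)
  drop[pmax(idx - 1L, 1L)] <- TRUE
  drop[pmin(idx + 1L, n)] <- TRUE
  out <- beats
  out$ectopic <- ect
  out$retained <- !drop
  out
}

#' Average retained beats into a 250-point representative beat
#'
#' Each retained beat is linearly resampled to 250 points on a normalized
#' beat-time axis \[0, 1\] and the resampled beats are averaged pointwise.
#'
#' @param rec The (filtered, offset-corrected) [catheter_recording()].
#' @param beats A `pv_beat_set` (after [flag_ectopy()]); only rows with
#'   `retained == TRUE` contribute.
#' @return A `pv_averaged_beat`: tibble with `t_frac` (250 points) and
#'   `pressure_mmhg`, plus attributes `n_beats_averaged`, `peak_sd` (SD of
#'   per-beat peak pressures, mmHg) and `beat_duration_s` (mean retained RR).
#' @export
average_beats <- function(rec, beats) {
  stopifnot(inherits(rec, "pv_recording"), inherits(beats, "pv_beat_set"))
  kept <- dplyr::filter(beats, .data$retained)
  if (nrow(kept) == 0L) {
    abort("No retained beats to average.", class = "pvloopr_empty_set")
  }
  t_out <- seq(0, 1, length.out = 250L)
  p <- rec$pressure_mmhg
  mat <- vapply(seq_len(nrow(kept)), function(i) {
    seg <- p[kept$onset[i]:kept$end[i]]
    stats::approx(seq(0, 1, length.out = length(seg)), seg, xout = t_out)$y
  }, numeric(250L))
  peaks <- apply(mat, 2L, max)
  new_tibble(
    tibble(t_frac = t_out, pressure_mmhg = rowMeans(mat)),
    n_beats_averaged = nrow(kept),
    peak_sd = if (nrow(kept) > 1L) stats::sd(peaks) else 0,
    beat_duration_s = mean(kept$rr_s),
    class = "pv_averaged_beat"
  )
}

#' Calibrate the conductance volume channel to a CMR end-diastolic volume
#'
#' Uniform rescaling so the largest conductance volume equals the
#' end-diastolic volume from the preceding CMR examination.
#'
#' @param rec A [catheter_recording()] with a `volume_cond` channel.
#' @param cmr_edv End-diastolic volume from CMR (mL).
#' @return The recording with `volume_cond` rescaled so its maximum equals
#'   `cmr_edv`.
#' @export
calibrate_conductance <- function(rec, cmr_edv) {
  stopifnot(inherits(rec, "pv_recording"))
  if (!"volume_cond" %in% names(rec)) {
    abort("Recording has no conductance volume channel.",
          class = "pvloopr_channel")
  }
  mx <- max(rec$volume_cond)
  if (!is.finite(mx) || mx <= 0) {
    abort("Conductance channel maximum must be positive.",
          class = "pvloopr_channel")
  }
  rewrap_recording(rec, volume_cond = rec$volume_cond * cmr_edv / mx)
}

#' Build the invasive-reference PV loop
#'
#' Pairs the averaged invasive pressure beat with the CMR volume curve, both
#' on a normalized beat-time axis anchored at end diastole (pressure beat
#' onset corresponds to the maximal-volume frame), and interpolates the paired
#' trajectory to the standard 100-point loop.
#'
#' @param avg A `pv_averaged_beat` from [average_beats()].
#' @param vol A [volume_curve()].
#' @return A `pv_loop` with `source = "invasive"`.
#' @export
build_reference_loop <- function(avg, vol) {
  stopifnot(inherits(avg, "pv_averaged_beat"), inherits(vol, "pv_volume_curve"))
  smry <- summarize_volumes(vol) # errors on a degenerate curve
  period <- attr(vol, "cycle_duration")
  # volumes on the averaged beat's 250-point normalized axis
  v250 <- periodic_spline_eval(vol$time_s, vol$volume_ml, period,
                               avg$t_frac * period)
  t_out <- seq(0, 1, length.out = 101L)[1:100]
  p100 <- stats::approx(avg$t_frac, avg$pressure_mmhg, xout = t_out)$y
  v100 <- stats::approx(avg$t_frac, v250, xout = t_out)$y
  new_pv_loop(t_out, v100, pmax(p100, 0), source = "invasive",
              heart_rate = attr(vol, "heart_rate"))
}

#' Full invasive pipeline: recording to reference loop
#'
#' Convenience composition of [lowpass_filter()], [correct_offset()],
#' [segment_beats()], [flag_ectopy()], [average_beats()] and
#' [build_reference_loop()].
#'
#' @param rec A raw [catheter_recording()].
#' @param vol The paired [volume_curve()].
#' @param cutoff Low-pass cutoff (Hz).
#' @param rr_tolerance,max_ectopic_fraction Passed to [flag_ectopy()].
#' @return A `pv_loop` with `source = "invasive"`.
#' @export
compute_reference_loop <- function(rec, vol, cutoff = 10, rr_tolerance = 0.20,
                                   max_ectopic_fraction = 0.25) {
  rec <- correct_offset(lowpass_filter(rec, cutoff = cutoff))
  beats <- flag_ectopy(segment_beats(rec), rr_tolerance = rr_tolerance,
                       max_ectopic_fraction = max_ectopic_fraction)
  build_reference_loop(average_beats(rec, beats), vol)
}
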