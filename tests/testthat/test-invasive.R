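truth <- make_ground_truth()

test_that("low-pass filter has unit DC gain and strong stopband attenuation", {
  n <- 2500
  t <- (0:(n - 1)) / 250
  const <- catheter_recording(
    tibble::tibble(time_s = t, pressure_mmhg = rep(50, n))
  )
  expect_equal(lowpass_filter(const)$pressure_mmhg, rep(50, n),
               tolerance = 1e-9)

  fit_amplitude <- function(x, f) {
    mid <- 500:2000 # steady-state region
    basis <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
    sqrt(sum(stats::lm.fit(basis, x[mid])$coefficients^2))
  }
  slow <- catheter_recording(
    tibble::tibble(time_s = t, pressure_mmhg = 50 + 10 * sin(2 * pi * 1 * t))
  )
  expect_equal(fit_amplitude(lowpass_filter(slow)$pressure_mmhg, 1), 10,
               tolerance = 0.5)
  fast <- catheter_recording(
    tibble::tibble(time_s = t, pressure_mmhg = 50 + 10 * sin(2 * pi * 40 * t))
  )
  expect_lt(fit_amplitude(lowpass_filter(fast)$pressure_mmhg, 40), 1)

  expect_error(lowpass_filter(const, cutoff = 200), "Nyquist")
})

test_that("withdrawal offset is subtracted from every sample", {
  rec <- make_catheter_recording(truth, n_beats = 5, peak_sd_1p96 = 0,
                                 noise_sd = 0, withdrawal_offset = 5, seed = 1)
  rec0 <- make_catheter_recording(truth, n_beats = 5, peak_sd_1p96 = 0,
                                  noise_sd = 0, seed = 1)
  corrected <- correct_offset(rec)
  expect_equal(corrected$pressure_mmhg, rec0$pressure_mmhg, tolerance = 1e-9)
  expect_equal(attr(corrected, "withdrawal_offset"), 0)
  # zero offset is the identity
  expect_equal(correct_offset(rec0)$pressure_mmhg, rec0$pressure_mmhg)
})

test_that("beat segmentation recovers the generator's beats and onsets", {
  # 20 identical beats at 75 bpm
  rec <- make_catheter_recording(truth, n_beats = 20, peak_sd_1p96 = 0,
                                 noise_sd = 0, seed = 2)
  b <- segment_beats(lowpass_filter(rec))
  expect_gte(nrow(b), 19)
  expect_lte(nrow(b), 20)
  expect_lte(max(abs(b$rr_s - 0.8)), 1.5 / 250) # about one sample
  # ground-truth onsets recovered within 3 samples
  err <- b$onset - attr(rec, "true_onsets")[seq_len(nrow(b))]
  expect_lte(max(abs(err)), 3)

  const <- catheter_recording(
    tibble::tibble(time_s = (0:999) / 250, pressure_mmhg = rep(20, 1000))
  )
  expect_error(segment_beats(const), class = "pvloopr_segmentation")
})

test_that("ectopic beats and their neighbours are discarded", {
  # 21 beats of which 1 ectopic: exactly 3 beats removed, 18 retained
  rec <- make_catheter_recording(truth, n_beats = 21, ectopic_beats = 1,
                                 seed = 5)
  b <- flag_ectopy(segment_beats(correct_offset(lowpass_filter(rec))))
  expect_equal(nrow(b), 21)
  expect_equal(sum(b$ectopic), 1)
  expect_equal(sum(!b$retained), 3)
  expect_equal(sum(b$retained), 18)
  # flagged beat is the injected one
  expect_equal(which(b$ectopic), attr(rec, "ectopic_beats"))

  # no ectopy: everything retained
  rec0 <- make_catheter_recording(truth, n_beats = 10, peak_sd_1p96 = 0,
                                  noise_sd = 0, seed = 3)
  b0 <- flag_ectopy(segment_beats(lowpass_filter(rec0)))
  expect_true(all(b0$retained))

  # half the beats deviant: the recording must be rejected
  onsets <- cumsum(c(1, rep(c(200, 120), 10)))
  fake <- catheter_recording(
    tibble::tibble(time_s = (0:3400) / 250,
                   pressure_mmhg = 50 + 40 * sin(2 * pi * (0:3400) / 160))
  )
  bs <- segment_beats(fake, onsets = onsets)
  expect_error(flag_ectopy(bs), class = "pvloopr_frequent_ectopy")
})

test_that("beat averaging is exact for identical beats and 250 points long", {
  rec <- make_catheter_recording(truth, n_beats = 12, peak_sd_1p96 = 0,
                                 noise_sd = 0, seed = 4)
  frec <- lowpass_filter(rec)
  beats <- flag_ectopy(segment_beats(frec))
  # drop the edge beats (trace-start onset, one-sample-short trailing beat)
  # so every retained segment is an identical interior copy
  beats$retained[c(1, nrow(beats))] <- FALSE
  avg <- average_beats(frec, beats)
  expect_equal(nrow(avg), 250)
  expect_equal(attr(avg, "n_beats_averaged"), sum(beats$retained))
  # identical beats: the average equals any single resampled beat
  one <- frec$pressure_mmhg[beats$onset[2]:beats$end[2]]
  one250 <- approx(seq(0, 1, length.out = length(one)), one,
                   xout = seq(0, 1, length.out = 250))$y
  expect_equal(avg$pressure_mmhg, one250, tolerance = 1e-9)
  expect_equal(attr(avg, "peak_sd"), 0, tolerance = 1e-9)

  # averaging commutes with a uniform pressure offset
  shifted <- catheter_recording(
    tibble::tibble(time_s = frec$time_s,
                   pressure_mmhg = frec$pressure_mmhg + 7)
  )
  avg_s <- average_beats(shifted, beats)
  expect_equal(avg_s$pressure_mmhg, avg$pressure_mmhg + 7, tolerance = 1e-9)

  empty <- beats
  empty$retained <- FALSE
  expect_error(average_beats(rec, empty), class = "pvloopr_empty_set")
})

test_that("averaged beat tracks the true beat closely without noise", {
  rec <- make_catheter_recording(truth, n_beats = 24, peak_sd_1p96 = 0,
                                 noise_sd = 0, seed = 1)
  avg <- average_beats(lowpass_filter(rec),
                       flag_ectopy(segment_beats(lowpass_filter(rec))))
  tb <- truth$beat$pressure_mmhg
  tb250 <- approx(seq(0, 1, length.out = length(tb)), tb,
                  xout = seq(0, 1, length.out = 250))$y
  # residual onset placement (~1-2 samples) dominates; see the vignette
  expect_lt(sqrt(mean((avg$pressure_mmhg - tb250)^2)), 4)
})

test_that("conductance calibration equalizes the maximum to the CMR EDV", {
  n <- 1000
  rec <- catheter_recording(
    tibble::tibble(time_s = (0:(n - 1)) / 250,
                   pressure_mmhg = 50 + 30 * sin(2 * pi * (0:(n - 1)) / 200),
                   volume_cond = 40 + 40 * cos(2 * pi * (0:(n - 1)) / 200))
  )
  cal <- calibrate_conductance(rec, cmr_edv = 336)
  expect_equal(max(cal$volume_cond), 336)
  expect_equal(cal$volume_cond, rec$volume_cond * 336 / 80, tolerance = 1e-12)
  # already calibrated: identity
  expect_equal(calibrate_conductance(cal, 336)$volume_cond, cal$volume_cond)

  no_chan <- catheter_recording(
    tibble::tibble(time_s = (0:99) / 250, pressure_mmhg = rep(50, 100))
  )
  expect_error(calibrate_conductance(no_chan, 336), class = "pvloopr_channel")
  zero <- catheter_recording(
    tibble::tibble(time_s = (0:99) / 250, pressure_mmhg = rep(50, 100),
                   volume_cond = rep(0, 100))
  )
  expect_error(calibrate_conductance(zero, 336), class = "pvloopr_channel")
})

test_that("reference loop reproduces ground-truth stroke work", {
  rec <- make_catheter_recording(truth, n_beats = 24, peak_sd_1p96 = 0,
                                 noise_sd = 0, seed = 1)
  ref <- compute_reference_loop(rec, truth$vol)
  expect_s3_class(ref, "pv_loop")
  expect_equal(nrow(ref), 100)
  expect_equal(attr(ref, "source"), "invasive")
  m <- compute_all_metrics(ref)
  expect_equal(m$sw, truth$true_metrics$sw,
               tolerance = 0.02 * truth$true_metrics$sw)
  expect_identical(m$pva, m$sw + m$pe)
})

test_that("a constant averaged pressure gives a loop with near-zero area", {
  rec <- make_catheter_recording(truth, n_beats = 6, peak_sd_1p96 = 0,
                                 noise_sd = 0, seed = 9)
  beats <- segment_beats(lowpass_filter(rec))
  flat <- catheter_recording(
    tibble::tibble(time_s = rec$time_s,
                   pressure_mmhg = rep(40, nrow(rec)))
  )
  avg <- average_beats(flat, beats)
  ref <- build_reference_loop(avg, truth$vol)
  expect_lt(stroke_work(ref), 1e-6 * 40 * 336)
})

test_that("the invasive pipeline is deterministic", {
  rec <- make_catheter_recording(truth, n_beats = 20, seed = 11)
  r1 <- compute_reference_loop(rec, truth$vol)
  r2 <- compute_reference_loop(rec, truth$vol)
  expect_identical(r1$pressure_mmhg, r2$pressure_mmhg)
})
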