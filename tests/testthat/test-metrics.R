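# 4-vertex rectangle loop: V in [100, 170], P in [10, 110]
rect_loop <- tibble::tibble(
  volume_ml = c(170, 100, 100, 170),
  pressure_mmhg = c(10, 10, 110, 110)
)

test_that("stroke work is the enclosed polygon area", {
  expect_equal(stroke_work(rect_loop), 7000)
  # degenerate loop
  expect_error(
    stroke_work(tibble::tibble(volume_ml = rep(100, 5),
                               pressure_mmhg = rep(50, 5))),
    class = "pvloopr_degenerate_loop"
  )
  # random convex polygons: shoelace equals fan triangulation
  for (seed in 1:10) {
    poly <- random_convex_polygon(100, seed)
    df <- tibble::tibble(volume_ml = poly$v, pressure_mmhg = poly$p)
    expect_equal(stroke_work(df), fan_area(poly$v, poly$p),
                 tolerance = 1e-9)
  }
})

test_that("ESPVR slope passes through the origin and the Emax point", {
  tri <- tibble::tibble(volume_ml = c(150, 50, 100),
                        pressure_mmhg = c(5, 100, 20))
  em <- espvr_slope(tri)
  expect_equal(em$espvr, 2)
  expect_equal(em$emax_volume, 50)
  expect_equal(em$emax_pressure, 100)
  # constant P/V ratio: tie broken at the earliest sample
  flat <- tibble::tibble(volume_ml = c(100, 120, 140),
                         pressure_mmhg = 2 * c(100, 120, 140))
  expect_equal(espvr_slope(flat)$emax_index, 1)
  expect_equal(espvr_slope(flat)$espvr, 2)
  expect_error(espvr_slope(tibble::tibble(volume_ml = c(-1, 2, 3),
                                          pressure_mmhg = c(1, 2, 3))),
               "positive")
})

test_that("ESPVR of a modelled loop recovers the scaled elastance peak", {
  truth <- make_ground_truth(edv = 300, ef = 30, hr = 72, t_es_frac = 0.40,
                             lvp_sys = 110, edp = 7.5)
  em <- espvr_slope(truth$true_loop)
  expect_equal(em$espvr, max(truth$scaled$e_abs), tolerance = 0.01)
})

test_that("potential energy is the ESPVR triangle area", {
  expect_equal(potential_energy(2.0, 50), 2500)
  expect_equal(potential_energy(1.5, 0), 0)
  expect_error(potential_energy(-1, 10), "non-negative")
})

test_that("arterial elastance is the Emax-to-EDV slope", {
  tri <- tibble::tibble(volume_ml = c(150, 50, 100),
                        pressure_mmhg = c(5, 100, 20))
  expect_equal(arterial_elastance(tri), 1.0)
  degen <- tibble::tibble(volume_ml = c(100, 90, 95),
                          pressure_mmhg = c(110, 50, 10))
  expect_error(arterial_elastance(degen),
               class = "pvloopr_degenerate_geometry")
})

test_that("efficiency, power and energy-per-volume follow their definitions", {
  expect_equal(derived_metrics(5000, 0, 70, 60)$ve, 1)
  expect_equal(derived_metrics(5000, 5000, 70, 60)$ve, 0.5)
  # unit conversion: 7500 mmHg.mL at 60 bpm is 7500 * 1.33322e-4 ~ 0.99992 W
  expect_equal(derived_metrics(7500, 0, 70, 60)$mep_w, 7500 * 1.33322e-4,
               tolerance = 1e-12)
  expect_error(derived_metrics(5000, 100, 0, 60), "sv > 0")
})

test_that("full metric set on the rectangle matches hand computation", {
  m <- compute_all_metrics(rect_loop, hr = 60)
  expect_equal(m$sw, 7000)
  expect_equal(m$espvr, 1.1)
  expect_equal(m$pe, 5500)
  expect_equal(m$pva, 12500)
  expect_equal(m$ve, 0.56)
  expect_equal(m$epev, 12500 / 70, tolerance = 1e-9) # 178.57 mmHg
  expect_equal(m$ea, 110 / 70, tolerance = 1e-9)
  expect_identical(m$pva, m$sw + m$pe)
})

test_that("metrics are invariant to vertex rotation and orientation", {
  poly <- random_smooth_loop(100, seed = 3)
  df <- tibble::tibble(volume_ml = poly$v, pressure_mmhg = poly$p)
  m0 <- compute_all_metrics(df, hr = 70)
  rot <- dplyr::bind_rows(df[31:100, ], df[1:30, ])
  m1 <- compute_all_metrics(rot, hr = 70)
  rev <- df[nrow(df):1, ]
  m2 <- compute_all_metrics(rev, hr = 70)
  for (k in c("sw", "pe", "pva", "espvr", "ea", "ve", "epev")) {
    expect_equal(m1[[k]], m0[[k]], tolerance = 1e-12)
    expect_equal(m2[[k]], m0[[k]], tolerance = 1e-12)
  }
})

test_that("metrics obey the volume-scaling law", {
  poly <- random_smooth_loop(100, seed = 5)
  df <- tibble::tibble(volume_ml = poly$v, pressure_mmhg = poly$p)
  m0 <- compute_all_metrics(df, hr = 70)
  m2 <- compute_all_metrics(
    tibble::tibble(volume_ml = 2 * poly$v, pressure_mmhg = poly$p), hr = 70
  )
  expect_equal(m2$sw, 2 * m0$sw, tolerance = 1e-12)
  expect_equal(m2$pe, 2 * m0$pe, tolerance = 1e-12)
  expect_equal(m2$espvr, m0$espvr / 2, tolerance = 1e-12)
  expect_equal(m2$ea, m0$ea / 2, tolerance = 1e-12)
  expect_equal(m2$ve, m0$ve, tolerance = 1e-12)
})

test_that("shoelace area equals the integrated P dV on smooth loops", {
  for (seed in 1:10) {
    poly <- random_smooth_loop(200, seed)
    df <- tibble::tibble(volume_ml = poly$v, pressure_mmhg = poly$p)
    expect_equal(stroke_work(df), trapz_pdv(poly$v, poly$p),
                 tolerance = 1e-6 * trapz_pdv(poly$v, poly$p))
  }
})

test_that("efficiency falls as potential energy grows at fixed stroke work", {
  ve <- vapply(c(0, 2000, 4000, 8000), function(pe) {
    derived_metrics(5000, pe, 70, 60)$ve
  }, numeric(1))
  expect_true(all(diff(ve) < 0))
})
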