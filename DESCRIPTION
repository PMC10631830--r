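Package: pvloopr
Title: Non-Invasive Left-Ventricular Pressure-Volume Loops from Imaging
    Volumes and Brachial Blood Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes left-ventricular pressure-volume (PV) loops without
    catheterization by coupling a time-resolved ventricular volume curve
    (typically from cine cardiac magnetic resonance segmentation) to a
    time-varying elastance model scaled to brachial blood pressure and a
    user-estimated end-diastolic pressure. Derives the standard loop
    energetics (stroke work, potential energy, pressure-volume area,
    end-systolic pressure-volume relationship slope, arterial elastance,
    ventricular efficiency, mean external power, energy per ejected
    volume). Also implements the invasive reference pipeline used to
    validate the method (10 Hz filtering, offset correction, beat
    segmentation, ectopy exclusion, multi-beat averaging to a 250-point
    representative beat), method-agreement statistics (linear regression,
    percent Bland-Altman bias with limits of agreement, paired t-tests,
    two-way random-effects absolute-agreement ICC), an end-diastolic
    pressure sensitivity sweep, and a seeded synthetic-data generator
    producing paired volume curves and multi-beat catheter pressure
    traces with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
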