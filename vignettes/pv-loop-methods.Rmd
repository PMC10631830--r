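---
title: "Non-invasive pressure-volume loops: model, pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive pressure-volume loops: model, pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvloopr)
```

## The problem

Left-ventricular pressure-volume (PV) loops are the reference description of
ventricular energetics: the loop area is stroke work (SW), the end-systolic
pressure-volume relationship (ESPVR) indexes contractility, and derived
quantities (pressure-volume area, ventricular efficiency, arterial elastance,
mean external power, energy per ejected volume) summarize the mechanical
state of the ventricle. Measuring them directly requires a catheter in the
left ventricle. `pvloopr` implements the non-invasive alternative: a
time-resolved LV volume curve (from cine CMR segmentation, typically 25
frames per cycle) is coupled to a time-varying elastance model scaled to a
brachial cuff pressure and a user-estimated end-diastolic pressure (EDP),
producing a modelled pressure trace and hence a full PV loop without
catheterization. The package also implements the invasive reference pipeline
and the method-agreement statistics needed to validate the approach, plus a
synthetic-data generator so the whole validation design can be exercised
end to end with known ground truth.

## The pressure model

Instantaneous elastance is the pressure-to-volume ratio referenced to the
volume-axis intercept $V_0$:

$$P(t) = E(t)\,\bigl(V(t) - V_0\bigr), \qquad V_0 = 0,$$

so $P(t) = E(t)V(t)$. The model has three ingredients.

**Normalized shape.** `default_elastance()` supplies a normalized elastance
$E_N(x)$ on cycle fraction $x \in [0,1]$, a double-Hill product

$$E_N(x) \propto
  \frac{(x/\tau_1)^{n_1}}{1 + (x/\tau_1)^{n_1}} \cdot
  \frac{1}{1 + (x/\tau_2)^{n_2}},
  \qquad \tau_1 = 0.269,\; n_1 = 1.32,\; \tau_2 = 0.452,\; n_2 = 21.9,$$

renormalized to a peak of 1 - a widely used analytic approximation of the
normalized human elastance waveform. The shape ships as a CSV asset
(`inst/extdata/elastance_default.csv`), so a user-digitized curve can be
dropped in via `read_elastance_csv()` or the `elastance_path` configuration
field without touching code.

**Temporal scaling.** The subject's end-systolic time is taken from imaging:
the cycle fraction of the minimal LV volume. The elastance curve is warped by
a piecewise-linear bijection of $[0,1]$ that maps the *middle of its
downslope* onto that fraction. "Middle of the downslope" is interpreted in
amplitude - the first point after the peak where $E_N = 0.5$ - rather than
as the temporal midpoint of the descent; the two differ little for the
packaged shape, and the amplitude definition is robustly computable on any
monotone descent.

**Amplitude scaling.** A pure multiplicative scale cannot match both a
systolic and a diastolic target, so scaling is affine,
$E(t) = E_0 + k\,\tilde E_N(t)$, with the normalized curve re-anchored
($\tilde E_N$ exactly 0 at the end-diastolic sample) and $E_0 = EDP/EDV$, so
the end-diastolic pressure is reproduced exactly. The systolic target is the
cuff estimate $LVP_{systole} = \tfrac{2}{3}SBP + \tfrac{1}{3}DBP$; $k$ is
solved by bisection on $\max_t E(t)V(t) = LVP_{systole}$ (the peak is
strictly increasing in $k$, bracket $[0,\,10\,LVP_{systole}/\min V]$, run to
bracket exhaustion, which leaves the peak within far less than the 0.05 mmHg
acceptance band). EDP is not measurable from a cuff; the default assumption
is 7.5 mmHg, and `edp_sensitivity_sweep()` quantifies how little the derived
metrics depend on it across 3-40 mmHg.

The loop itself is the pressure-volume trajectory interpolated linearly in
cycle fraction to exactly 100 points. After interpolation the pressures are
recalibrated affinely about EDP so that the maximum over the 100 returned
samples - not just over the dense internal grid - equals the systolic
target; without this the sampled peak can fall short by a few tenths of a
mmHg when the true peak lands between output samples.

## Loop metrics

All metrics are computed from the discrete loop samples, identically for
non-invasive and invasive loops:

* **SW**: absolute shoelace (polygon) area of the $(V, P)$ vertex sequence;
  orientation-independent.
* **Emax point**: sample with the maximal $P/V$ ratio ($V_0 = 0$); ties go to
  the earliest sample. **ESPVR** is the slope through the origin and that
  point.
* **PE**: triangle area $\tfrac12\,ESV\,(ESPVR \cdot ESV)$; **PVA** = SW + PE
  holds exactly by construction.
* **Ea**: slope from the Emax point to $(EDV, 0)$, i.e.
  $P_{Emax}/(EDV - V_{Emax})$. The looser shorthand "$E_{max}/SV$" seen in
  the clinical literature is dimensionally inconsistent with the slope
  definition unless $V_{Emax} = ESV$; the slope definition is implemented
  (the two coincide numerically when the Emax point sits at end systole).
* **VE** = SW/PVA; **EPEV** = PVA/SV; **MEP** = SW·HR/60, reported both in
  raw mmHg·mL/min and in watts (1 mmHg·mL = 1.33322e-4 J).

## The invasive reference pipeline

Catheter pressure recordings (nominally 250 Hz, ~1 min) are processed as:
zero-phase second-order Butterworth low-pass at 10 Hz (applied
forward-backward; order chosen for minimal ringing, the effective two-pass
attenuation one octave above cutoff is ~25 dB), withdrawal-offset
subtraction, beat segmentation, ectopy exclusion, and averaging of the
retained beats, each linearly resampled to 250 points on a normalized
beat-time axis.

**Onset detection.** Beat onsets must mark end diastole, because the
averaged pressure beat is paired with the volume curve anchored at the
R-wave. On an LV trace the *global* inter-beat pressure minimum sits in
early diastole (pressure creeps upward through filling toward EDP), about
half a cycle before the upstroke, so "minimum before the upstroke" is not an
ED marker. Instead the onset is the foot of the systolic upstroke by the
intersecting-tangent construction standard in pressure-waveform analysis:
the tangent at the maximal-dP/dt sample extrapolated down to the level of
the local minimum immediately preceding the upstroke. Either landmark alone
is biased (the local minimum early, a slope threshold late - the modelled
systolic rise starts with zero slope); the tangent crossing recovers the
generator's true onsets to about one sample at 250 Hz. Automatic markers can
be overridden through the `onsets` argument, the programmatic stand-in for
the manual marker check performed on real recordings.

**Ectopy.** Identification is by RR deviation: a beat whose preceding
onset-to-onset interval deviates from the median by more than 20%
(configurable) is ectopic, and the ectopic beat plus both neighbours are
dropped - one injected ectopic therefore removes exactly three beats. If
more than 25% of beats are ectopic the recording is rejected outright,
mirroring the exclusion of high-ectopic-burden recordings in practice.

**Pairing with volumes.** The averaged 250-point beat and the
(periodic-spline resampled) volume curve share the normalized beat-time
axis, both anchored at end diastole, with no lag optimization; the paired
trajectory is then interpolated to the standard 100-point loop. The
conductance volume channel, when present, is only rescaled so its maximum
equals the imaging EDV; conductance-to-volume physics is out of scope.

## Agreement statistics

`compare_methods()` composes, per metric across paired datasets: OLS
regression of method A on method B ($R^2$, slope, intercept, F-test p);
percent Bland-Altman (per-pair difference relative to the pairwise mean -
the standard convention; a reference-denominator variant is selectable -
with limits of agreement at bias ± 1.96 sample SD, no small-sample t
correction); a paired t-test (identical arrays return $t=0$, $p=1$; a
constant non-zero shift returns the $p \to 0$ limit, since `t.test` refuses
zero-variance differences); and ICC(2,1) - two-way random effects, absolute
agreement, single measures - computed from the ANOVA mean squares
$$ICC = \frac{MS_R - MS_E}{MS_R + MS_E + 2\,(MS_C - MS_E)/n}.$$
Whether a published ICC is single-measures or average-measures is often
ambiguous; single measures is the conservative choice implemented here. No
multiple-testing correction is applied across the seven metrics.

## The synthetic generator

`make_volume_curve()` builds a smooth 25-frame cycle: cosine ejection to ESV
at the requested end-systolic fraction, a short isovolumic plateau (so the
sampled minimum equals ESV exactly even off-grid), then biphasic refill
(rapid early filling, diastasis, atrial kick). `make_ground_truth()` derives
the true scaled elastance, pressure beat, loop and metrics from known
parameters; `make_catheter_recording()` concatenates beats at 250 Hz with
per-beat peaks drawn around the true peak at 1.96 SD = 6.1 mmHg (the
beat-to-beat loading variability observed within clinical recordings), 1
mmHg additive sample noise, and ectopics realized as short-coupled beats
(preceding diastole truncated to 0.6 RR, peak reduced 30%, timing not
compensated - so exactly one RR interval deviates per ectopic).
`make_cohort()` draws haemodynamic states across EDV 150-400 mL, EF 15-45%,
HR 60-90 bpm, peak pressure 90-140 mmHg and end-systolic fraction
0.35-0.45 - deliberately wide, spanning dilated failing ventricles - and
inverts the cuff formula around the true peak plus an optional +11 mmHg
brachial bias (cuff pressures overestimate invasive peaks), jittered N(1,
0.2) per dataset. The true and assumed EDP both default to 7.5 mmHg
(self-consistency); a `shape_mismatch` mode generates truth from a perturbed
elastance (power transform of the shape) to emulate model error.

What the generator does *not* emulate: respiratory modulation, Windkessel
afterload coupling, baseline drift, valvular gradients, and real
segmentation error in the volume curves. Passing the synthetic validation
therefore shows the pipeline is internally consistent and numerically
correct under the stated noise model - not that the elastance family matches
any given patient; that question is exactly what the invasive validation
design answers on real data.

## Numerical choices and degenerate inputs

* Volume interpolation is periodic cubic spline (retrospective gating closes
  the cycle); loop and beat interpolation are linear, matching the
  100-point / 250-point conventions.
* Ties on the minimal volume and on the maximal $P/V$ ratio go to the
  earliest sample.
* A constant volume curve is a degenerate input for the loop pipeline
  (SV = 0) and raises a typed error; `scale_amplitude()` itself accepts it,
  where the closed form $k = (LVP_{systole} - EDP)/EDV$ applies.
* Non-ED-gated volume curves (maximal volume away from frame 0) produce a
  warning and the ED frame is recorded; the cycle is not re-anchored.
* $V_0$ is fixed at 0 mL; it is not exposed as a fitted parameter.
* Bisection runs at most 200 iterations and verifies the 0.05 mmHg target;
  failure raises a typed numerical error rather than returning silently.

## Problem sizes used in the tests

The test suite and acceptance checks run entirely on generated data: random
loop geometries with 100-200 vertices (against fan-triangulation and
trapezoidal $\oint P\,dV$ oracles), 50-case random grids for the pressure
anchoring contract, 8-dataset cohorts for parameter recovery and method
agreement, 20-24-beat recordings for the invasive pipeline, and 100-seed
Monte-Carlo replicates for the averaging-noise bound. These sizes keep the
full suite under a minute while leaving each statistical check comfortably
powered for its tolerance.

## Known limitations

* The cuff-to-ventricle formula ignores peripheral pulse amplification and
  any delay between cuff measurement and imaging; no drift correction is
  attempted.
* Single-beat ESPVR through the origin is a simplification: no patient
  $V_0$, no nonlinear end-systolic relation across loading states, and no
  dP/dt-based indices.
* The averaged invasive beat and the volume curve are aligned by normalized
  cycle fraction only; residual onset-placement error of one to two samples
  propagates into reference-loop metrics at the 1-5% level, which bounds how
  tightly the synthetic validation can close (see the averaging tests).
* Conductance-catheter volume calibration beyond EDV equalization is out of
  scope.
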