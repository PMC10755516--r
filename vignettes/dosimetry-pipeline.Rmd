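---
title: "Organ dosimetry for multi-cycle Lu-177 radioligand therapy"
author: "rltdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ dosimetry for multi-cycle Lu-177 radioligand therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rltdose)
```

## The problem

Patients treated with Lu-177-labelled radioligands (for instance
PSMA-targeted therapy in metastatic castration-resistant prostate cancer)
receive several administrations, typically 7.4 GBq per cycle for up to six
cycles. The organs at particular risk of radiotoxicity — kidneys, lacrimal
glands, salivary glands, and red marrow — accumulate radiation dose across
cycles, and clinical protocols compare the cumulative kidney dose against
limits inherited from external-beam experience. Full multi-time-point
imaging in every cycle is burdensome for patients who are often in poor
health, so a practical design images the complete time–activity curve only
in cycle 1 and a single time point (nominally 48 h) in later cycles.

`rltdose` implements that design end to end:

1. fit cycle-1 organ time–activity curves and integrate them
   (time-integrated activity, TIA);
2. derive cycles-2+ TIAs from the single measurement by rescaling the
   cycle-1 curve;
3. convert TIAs into absorbed doses through the MIRD schema
   (`D(target) = sum over sources of TIA(source) x S(target <- source)`),
   with a unit-density sphere model for the lacrimal glands and the
   blood-based method for red marrow;
4. extrapolate cycle-1 doses to a predicted cumulative dose, accumulate the
   observed per-cycle doses, and compare the two across the at-risk organs
   with paired Hotelling T-squared tests (Bonferroni-adjusted);
5. summarize blood pharmacokinetics noncompartmentally.

A calibrated synthetic-cohort generator reproduces the study design and
carries exact ground truth, so every stage can be validated by parameter
recovery.

## Time–activity model and fitting

Organ activity is modelled as a sum of exponentials,
`A(t) = sum_i a_i exp(-lambda_i t)` (MBq, hours). Fitting minimizes the sum
of squared *relative* residuals `(1 - A(t_i)/y_i)^2`: organ activities span
two orders of magnitude between 2 h and 168 h, and relative weighting treats
each time point's quantification error as proportional, which matches how
SPECT quantification uncertainty behaves. Under multiplicative lognormal
noise this is close to the maximum-likelihood fit. Zero-activity points
carry no relative information and are excluded; a curve needs at least two
positive measurements at distinct times.

**Model selection.** With fewer than four points only a mono-exponential is
fitted. With four or more, a biexponential (which may have one negative
amplitude, describing uptake followed by washout) is *entertained* only when
the mono fit's relative RMS residual exceeds a noise gate (default 0.2,
i.e. twice a typical 10% quantification CV). The winner is then chosen by
corrected AIC on the relative residuals. Two details deserve comment:

* A four-parameter biexponential meeting exactly four points can always
  interpolate them, so any purely RSS-based criterion would select it even
  when the "structure" it fits is pure measurement noise. The noise gate
  encodes the measurement-uncertainty scale and keeps the parsimonious model
  whenever the mono residuals are consistent with noise, while still
  selecting the biexponential whenever the data genuinely rise and fall
  (uptake-phase curves fail the gate by a wide margin).
* The AICc small-sample correction `2k(k+1)/(n-k-1)` is undefined at
  `n = 4, k = 4`; the implementation floors the denominator (default 0.5)
  so the criterion stays finite for degree-of-freedom-exhausted fits.

**Physical constraints.** The terminal (smallest) rate is clamped to the
physical decay constant of the nuclide — an effective half-life longer than
the physical half-life is impossible — and the amplitudes are refitted by
linear least squares when the clamp binds. A selected biexponential must be
non-negative on a dense grid over ten physical half-lives; otherwise the
mono fit is kept. Biexponential optimization uses Levenberg–Marquardt with
a deterministic multi-start list (terminal-phase curve peeling plus a fixed
grid of fast rates), so fits are bit-reproducible.

## Time-integrated activity

Two integrators are provided:

* **analytic** (default): `sum(a_i / lambda_i)`, the closed-form integral of
  the fitted curve over `[0, Inf)`;
* **hybrid**: fitted-curve integral from 0 to the first measurement,
  trapezoid over the observed range, analytic tail
  `A_last / lambda_terminal` beyond the last point.

The analytic mode is the default for a quantitative reason. At the sparse
late schedule (48 h and 168 h points, effective half-lives around 80 h) the
trapezoid on the convex decaying curve overestimates the 48–168 h segment by
roughly `(lambda h / 2) coth(lambda h / 2) - 1`, about 8–9%, which is about
4% of the total TIA — an avoidable systematic error an order of magnitude
larger than the fit noise. The hybrid integrator is retained as an option
(it is less model-dependent when a curve shape is in doubt) and both values
are recorded in the fit log; the package's tests verify that the two agree
within the trapezoid convexity bound and converge as sampling densifies.

## Single-time-point scaling

For cycle `k >= 2` the TIA is the cycle-1 TIA rescaled by the activity
ratio at the measurement time:
`TIA_k = TIA_1 x A_k(t) / A_1_fitted(t)` — the whole cycle-1 curve shape is
reused, not a one-point closed-form approximation. The denominator is the
*fitted* cycle-1 value, which suppresses cycle-1 measurement noise and is
available at the 24 h fallback time. If the true cycle-k curve is an exact
scalar multiple of cycle 1, the method is exact; if the washout rate changes
by a factor `r`, the relative error is `(lambda_k/lambda_1)
exp(-t_s (lambda_k - lambda_1))` at scaling time `t_s` (about +10% / −13%
for ±20% rate changes at 48 h), which the tests pin against the closed form.

One exception: the **whole-body** region is a sum of many compartments with
different rates, which a low-order fitted curve represents only
approximately. Its cycle ratio is therefore taken from the *measured*
values at matched nominal times (48 h vs the cycle-1 48 h point; the fitted
denominator is used only when the times differ, e.g. a 24 h fallback). This
keeps the remainder-of-body and red-marrow scaling exactly proportional
when the kinetics are, at the cost of slightly more noise sensitivity than
the fitted denominator.

## Dose engine

Units are fixed package-wide: activity MBq, time h, S values mGy/(MBq.h),
doses Gy; the single mGy-to-Gy conversion lives in one internal function.

* **MIRD sum**: `organ_dose()` evaluates
  `D = sum_s TIA(s) S(T <- s) / 1000` over the supplied sources, including
  `remainder_of_body` (whole-body TIA minus the modelled organs, validated
  non-negative).
* **S values** are data, not physics computed here. The packaged fixture
  (`smatrix_lu177()`) is a *synthetic* male-phantom-like matrix built from
  explicit energy bookkeeping — 147.9 keV non-penetrating energy per decay
  (mean beta plus conversion/Auger electrons), ~31 keV photon energy per
  decay, reference-man-like organ masses, full local absorption of
  electrons, small photon cross-absorption fractions. It reproduces the
  self-dose-dominated structure of Lu-177 dosimetry and is clearly labelled
  synthetic; for clinical work, supply a phantom-derived matrix via
  `read_smatrix()`.
* **Lacrimal glands** are far below phantom resolution, so their dose uses
  the unit-density sphere model
  `D = phi x Delta_np x TIA / m` with defaults `m = 0.7 g` (configurable —
  reported gland masses vary substantially between patients) and electron
  absorbed fraction 0.90 for a sphere of that size.
* **Red marrow** uses the blood-based method: marrow activity concentration
  equals blood concentration times the red-marrow-to-blood ratio (default
  1.0, the standard value for agents without specific marrow binding);
  the dose adds marrow self-dose and a remainder-of-body cross-dose term,
  reported separately. Blood concentration is fitted from the cycle-1
  samples (excluding the pre-dose and immediate post-administration draws)
  and integrated analytically; later cycles scale the marrow dose with the
  whole-body imaging ratio, since circulating activity is not re-sampled
  after cycle 1.

## Predicted vs observed cumulative doses

The predicted cumulative dose is a pure extrapolation,
`d_1 (Gy/GBq) x planned total activity` (44.4 GBq at the defaults); the
observed value is the sum of per-cycle doses and is reported for
*completers* only — patients with dosimetry in every planned cycle — so the
observed column is not diluted by partial courses. Relative difference is
`100 (predicted - observed)/observed`, signed so that over-prediction is
positive.

Predicted and observed are compared per cycle with a paired one-sample
Hotelling T-squared test on the difference vectors across the at-risk
organs: `T2 = n dbar' S^-1 dbar`, `F = T2 (n-p)/(p(n-1))` on `F(p, n-p)`.
The Bonferroni family size defaults to 5, one test per cumulative
comparison at cycles 2–6. Differences that are zero to within `1e-9` of the
dose scale short-circuit to `T2 = 0, p = 1` instead of inverting a
numerically degenerate covariance (this happens for noiseless proportional
cohorts); a genuinely singular covariance is an error suggesting a smaller
organ subset.

## Blood pharmacokinetics

`nca()` reports Cmax/Tmax from the observed maxima and the terminal rate
`lambda_z` from a log-linear fit over a terminal tail. The tail is chosen
among contiguous point sets ending at the last sample (length at least 3,
starting after Tmax, excluding samples at or before 0.05 h) by maximum
adjusted R-squared — a conventional, deterministic rule; the exact rule a
given clinical analysis used is rarely stated, and alternatives (fixed last
three points) agree within a few percent at this sampling schedule.
Geometric summaries use `exp(mean(log v))` and
`100 sqrt(exp(s^2) - 1)` with `s` the SD of the logs.

## The synthetic cohort generator

The generator is the package's test bed and emulates the study conditions
as defaults, not as tunable conveniences:

* 30 patients, 7.4 GBq per cycle, up to 6 cycles; imaging at
  {2, 24, 48, 168} h in cycle 1 and 48 h in cycles 2–6 (one patient imaged
  at 24 h in cycle 2); blood samples at pre-dose, 1 min, 20 min, and 1, 2,
  4, 24, 48, 72, 144 h in cycle 1 only.
* Attrition fixed at 29/21/21/19/13/10 evaluable patients in cycles 1–6,
  assigned by patient index so runs are reproducible; the ten completers
  are patients 1–10.
* Organ kinetics: instantaneous uptake followed by mono-exponential
  biological washout times physical decay, so every effective half-life is
  below the physical one by construction. Uptake amplitudes and washout
  half-lives are lognormal across patients. The *median* amplitudes are
  calibrated in closed form (`f = d lambda_eff / S_self`) so that the median
  patient reproduces the published per-cycle dose-per-activity means for
  each organ given the packaged S fixture, and the lognormal spread is set
  from the published between-patient CVs (washout variability, CV 15%,
  absorbs part of it). Biological washout half-lives (25–80 h depending on
  organ) are physiologically chosen, not fitted.
* Blood: biexponential decline with a short absorption/mixing factor
  peaking near 20 min, distribution volume ~6 L, fast phase ~1.2 h, and a
  terminal half-life sampled lognormally around a 41.6 h geometric mean
  with 68.8% geometric CV (clamped at the physical half-life). The terminal
  weight is solved in closed form so the median red-marrow dose per unit
  activity is 0.035 Gy/GBq.
* Noise and cycle effects: multiplicative lognormal measurement noise
  (default CV 10%, a SPECT-quantification level) and lognormal inter-cycle
  perturbations of uptake and washout (default CV 20%). Both default
  choices are declared, since the study itself publishes no noise model.

What the generator does **not** emulate: image formation and quantification
(partial-volume effects, contouring variability, organ-mass errors),
correlated kinetics between organs, informative dropout (sicker patients
leaving earlier with different kinetics), tumour uptake competing with
normal organs, or urine data. Passing recovery tests therefore demonstrates
the *computational* correctness of the pipeline under the declared error
model — they do not certify accuracy on real patient data, where
quantification bias typically dominates.

## Numerical choices

* Mono fits: Gauss–Newton on relative residuals from the log-linear OLS
  start; step tolerance `1e-12`, at most 100 iterations. On noiseless data
  this converges to machine precision, which is what makes the
  proportional-kinetics exactness property hold to `1e-9` through the full
  pipeline.
* Biexponential multi-start: fixed, deterministic start list; LM tolerances
  `1e-15`.
* Scale-factor floor: a fitted cycle-1 activity below `1e-9` of the curve
  amplitude is unscalable (error rather than a wild ratio).
* Problem sizes in the test suite (chosen to exercise the statistics at
  meaningful precision): 200 simulated cohorts for recovery bias and for
  the calibration check; 2000 replicates for Hotelling type-I calibration
  at n = 10, p = 4.
* All randomness flows from explicit seeds; the generator restores the
  caller's RNG state.

## Known limitations

* The S fixture is synthetic; absolute doses from it are structurally
  plausible but not phantom-accurate. Supply a real S matrix for clinical
  interpretation.
* Cycles 2+ are never re-fitted; if a patient's kinetics change shape (not
  just scale) between cycles, the single-time-point method inherits the
  corresponding bias, which the scaling-error tests quantify for rate
  perturbations.
* The blood-based marrow method assumes no specific marrow binding
  (RMBLR 1.0) and scales later cycles by whole-body imaging, both standard
  but unverifiable without per-cycle blood sampling.
* Observed cumulative doses are defined for completers; cohorts with heavy
  attrition compare a 29-patient predicted mean with a 10-patient observed
  mean, and part of any predicted-observed gap is a selection effect — the
  same caveat applies to the published design this package emulates.
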