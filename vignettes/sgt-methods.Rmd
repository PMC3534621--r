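---
title: "The Start Growth Time method: model, calculus and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Start Growth Time method: model, calculus and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgtkit)
```

## The measurement model

A bacterial culture diluted into fresh medium regrows exponentially until it
approaches stationary phase. If $N_0$ live cells/mL are inoculated and the
doubling time is $t_d$, the culture reaches the cell density $N_{thr}$ at
which its OD600 crosses a detection threshold after

$$\mathrm{SGT} = t_d \log_2 \frac{N_{thr}}{N_0}.$$

SGT (Start Growth Time) is therefore *affine in* $\log_{10} N_0$ with slope
$-t_d \log_2 10$ hours per decade. Two consequences drive everything in this
package:

1. **Counting.** A dilution series of known concentrations defines a linear
   calibration of SGT against $\log_{10}(\mathrm{CFU/mL})$, which can be
   inverted to read absolute live-cell concentrations off a plate reader —
   only live cells regrow, so dead cells and debris do not bias the count.
2. **Relative survival.** Differences of SGTs are differences of
   $\log_2 N_0$ scaled by $t_d$. After a bactericidal treatment, the delay of
   the treated aliquot relative to an untreated, identically diluted
   *normalizer* aliquot ($\Delta\mathrm{SGT}$), referenced against the same
   quantity in a *calibrator* sample ($\Delta\Delta\mathrm{SGT}$), yields a
   fold change $F = 2^{-\Delta\Delta\mathrm{SGT}}$ — the ΔΔCt recipe of qPCR
   with growth time in place of cycle number.

### Assumptions

* Calibrator and samples grow under the same conditions with similar doubling
  times; SGT differences are meaningful only on a shared $t_d$.
* OD is proportional to cell density between the threshold and the
  calibration range; the threshold sits just above instrument background, at
  the start of log phase.
* Survivors of the treatment resume growth with the same lag as the
  normalizer. Slow "awakening" inflates SGT and mimics fewer survivors;
  `quantify_survival()` surveils for this by comparing the apparent doubling
  time of the treated and normalizer arms of each sample
  (`slope_warn_factor`, default 1.5) and warning when they diverge, but it
  does not correct for it.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold` | 0.15 | OD600 | just above background at the start of log phase; results are meaningful over roughly 0.15–0.2, and the value is always recorded in outputs |
| `consecutive` | 2 | reads | a crossing must hold for two consecutive reads, so a single noisy spike cannot trigger detection |
| `mode` | `"paper"` | — | exponentiates ΔΔSGT in hours, the field's reporting convention; `"doublings"` divides by $t_d$ first so $2^{-\Delta\Delta SGT}$ is a true cell-count ratio |
| `dilution_factor` | 500 | — | the post-treatment dilution that outgrows antibiotic carryover; it cancels between arms and never enters the arithmetic, but the design errors if the two arms differ, since unequal dilutions would bias every ΔSGT by $\log_2(\text{ratio}) \cdot t_d$ |
| `window` (doubling-time fit) | threshold to 4× threshold | OD600 | the early log-linear phase just above detection, before saturation bends the curve |

Replicate aggregation uses the sample standard deviation ($n-1$); a
single-replicate group reports `sd = NA` rather than 0 — honesty over
convenience. All error propagation is in quadrature, and fold-change
uncertainty uses the delta method ($\mathrm{sd}_F = F \ln 2 \,
\mathrm{sd}_{\Delta\Delta}$).

### Unit convention for the exponent

Exponentiating ΔΔSGT measured in *hours* equals a cell-count ratio only when
$t_d = 1$ h. The default `"paper"` mode reproduces the field's convention
verbatim; `"doublings"` mode is the physically calibrated alternative and is
what the simulation studies validate against ground truth. The mode is
recorded in every output row so the two are never silently mixed. When
`doubling_time_hours` is not supplied in doublings mode, it is estimated from
the calibrator's normalizer curves; supplying an independently calibrated
value (e.g. from `doubling_time_from_slope()` of a dilution-series fit) is
preferred.

## Censoring

A well that never reaches the threshold within the observation window has no
SGT — only a lower bound, the last observed time. Such results are flagged
`censored` and the flag propagates: any censored input to
`delta_sgt()`/`delta_delta_sgt()` yields a flagged, non-numeric result, and
`aggregate_replicates()` excludes censored members from group means with a
warning (a fully censored group is itself censored). Nothing downstream ever
silently converts a lower bound into a number.

## Numerical choices

* **Interpolation.** The crossing time is linearly interpolated between the
  last sub-threshold read and the first read of the qualifying run. On a
  15-min read cadence this reduces to the conventional read-resolution SGT
  while being strictly more precise; on fine grids the interpolation error is
  $\approx r\,\Delta t^2/8$ (r = growth rate), which the oracle tests bound
  below $10^{-3}$ h at $\Delta t = 0.01$ h.
* **Blank handling.** If the plate map declares blank wells, their
  per-timepoint *median* is subtracted from sample wells (robust to a single
  contaminated blank); values are not clipped, and the `blank_corrected` flag
  makes double correction an error. Whether to blank-correct before
  thresholding is left to the user — both behaviours are available, and with
  a threshold set above background the conclusions are robust either way.
* **Regression direction.** Calibration regresses SGT on
  $\log_{10}(\mathrm{CFU/mL})$ (the known concentrations are the predictor);
  inversion is analytic, and intervals come from the delta method on the
  log10 scale — adequate for series of ≥ 6 points and far cheaper than a
  bootstrap. Extrapolation outside the fitted SGT range is refused unless
  explicitly requested.
* **Smoothing.** None by default; an optional moving median of window 3
  (`smooth = TRUE`) is available for noisy readers.

## What the simulator emulates — and what it does not

`simulate_growth()` draws logistic growth
$N(t) = K N_0 e^{rt'} / (K + N_0(e^{rt'} - 1))$, $r = \ln 2 / t_d$, with
$N$ held at $N_0$ through the lag phase ($t' = t - \mathrm{lag}$): cells
exist before growth resumes, so the pre-lag OD contribution is retained.
OD is $\mathrm{bg} + \alpha N(t)$ under mean-one lognormal multiplicative
noise (CV 5%) plus additive Gaussian read noise (sd 0.005 OD). Defaults:
$\alpha = 5 \times 10^{-10}$ OD·mL/cell, so OD 2.0 corresponds to
$\approx 4 \times 10^9$ cells/mL, the CFU-anchored density of a dense
culture; $K = 5 \times 10^9$ cells/mL; background 0.04; reads every 0.25 h
for 24 h; $t_d = 0.5$ h, a fast-growing rich-medium culture. Inocula below
1000 cells/mL are Poisson-sampled, reproducing the large relative error of
counting statistics at low dilutions (and occasionally sterile wells in kill
assays, which surface as censored results). Seeds are mandatory; identical
parameters and seed give bit-identical plates.

Not emulated: mechanistic kill kinetics during antibiotic exposure (the
surviving fraction is an input, not an output), diauxic/biphasic growth,
medium-dependent lag-phase effects, spatial plate artefacts (edge
evaporation, condensation), and reader drift. Passing tests therefore
demonstrate the *calculus* is right and robust to read noise and counting
statistics — not that any particular wet-lab system satisfies the model's
assumptions; a single SGT-versus-CFU calibration per growth condition
remains the way to establish that.

## Study sizes used in the validation suite

The test suite and `scripts/acceptance.R` use desk-scale designs chosen to
exercise every claim while completing in seconds: 8-point 1:10 dilution
series from $4 \times 10^7$ cells/mL over 10 seeds for calibration
linearity; 60 random $(N_0, t_d)$ combinations against the closed-form
oracle; 100 seeded kill assays (3 replicates per arm, surviving-fraction
ratios 2/8/32 against a $10^{-3}$ calibrator) for fold-change recovery; and
100 paired simulations at 40 vs 400 cells/mL for the sensitivity ordering.
The doublings-mode recovery study passes the simulation's known
$t_d = 0.5$ h through the assay design, as a practitioner would supply an
independently calibrated doubling time.

## Known limitations

* The hour-valued `"paper"` fold change is unit-dependent; cross-study
  comparisons should use doublings mode or report ΔΔSGT with $t_d$.
* Censored (never-growing) wells bound survival from above but the pipeline
  does not compute a formal censored-data estimate; heavily censored designs
  need longer observation windows.
* Conditions that alter lag phase (e.g. minimal media) shift SGT
  independently of inoculum; one calibration per condition is required, and
  cross-condition correction is out of scope.
* Awakening-kinetics bias is detected (slope surveillance) but not corrected.
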