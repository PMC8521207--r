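---
title: "Computing and quality-controlling cholesterol efflux capacity from plate assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and quality-controlling cholesterol efflux capacity from plate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecflux)
```

## The measurement problem

Cholesterol efflux capacity (CEC) quantifies how well a serum acceptor —
in practice the HDL-containing fraction left after apoB depletion —
extracts labelled cholesterol from cultured macrophages. Cells carrying a
fluorescent cholesterol analogue are incubated with the acceptor in
96-well plates; after a fixed time the label is split between the
supernatant (effluxed) and the cell layer (retained), and CEC is the
effluxed percentage of the total label. Two referencing conventions are
in use, and they are not interchangeable:

* **per-well**: each well is referenced to its own total recovered
  fluorescence,
  $$\mathrm{CEC}_{pw} = 100\cdot\frac{FI_{sup}}{FI_{sup}+FI_{lys}},$$
  which requires lysing every well but cancels well-to-well differences
  in cell number, staining and reader gain exactly;
* **time-zero (t0)**: each well is referenced to the mean fluorescence of
  control wells lysed at time zero,
  $$\mathrm{CEC}_{t0} = 100\cdot\frac{FI_{sup}}{FI_{t0}},$$
  which needs no per-well lysate read but inherits every error that makes
  the three t0 wells unrepresentative of the incubated wells.

In both cases the background fluorescence of unstained cells is first
subtracted from each read, and the passive efflux — label released to
acceptor-free medium — is subtracted from the resulting CEC. The package
computes both statistics from the same validated well records
(`compute_wells()`), flags rather than repairs pathological wells, and
carries the comparison statistics used to decide between the two
conventions.

## Processing rules and their rationale

**Background** is estimated per plate and per read type as the mean of at
least three unstained-cell wells, because reader gain is set per plate. A
net fluorescence below zero invalidates the well instead of being clamped
to zero: a reading under background indicates a failed well, and clamping
would bias CEC upward.

**The t0 reference** is the mean (not median) of the three t0-control
wells, matching the mean-based treatment of triplicates everywhere else;
its CV is reported and a CV above the replicate threshold raises a
warning. A non-positive reference makes the whole plate unusable for the
t0 method. t0 values above 100% are arithmetically legal and are
returned with an over-range flag.

**Passive efflux** is the mean raw CEC of at least three acceptor-free
wells under the matching method, subtracted from sample CEC. Negative
final CEC values are retained, again to avoid one-sided truncation. The
replicate CV used for rejection is computed on *pre*-passive raw CEC:
passive subtraction shifts means toward zero and would blow up the CV of
low-efflux samples whose absolute scatter is unchanged (`qc_config()`
exposes the switch).

**Rejection rule.** A sample is rejected when the CV of its replicates
strictly exceeds 15%; a CV of exactly 15.0% passes. All SDs and CVs in
the package use the sample (n−1) denominator, and tabulated percentages
round half-up (`round_half_up()`), so a printed 65% reduction recomputes
from its unrounded pair.

**Plate correction.** Four dedicated control sera are measured on every
plate. For each, the relative difference between its expected and
observed CEC is computed, and the mean over the four controls gives the
plate factor $1 + \overline{(obs-exp)/exp}$; all CEC on the plate is
divided by it. Averaging four controls keeps the factor robust to one
aberrant control (a rejected control drops out; below three the plate
stays uncorrected and flagged). The correction is multiplicative rather
than additive: it preserves positivity, the percent-of-total scale and
all within-plate ratios, and it removes a noise-free multiplicative
plate effect exactly — a property the test suite asserts to machine
precision. Expected values default to each control's across-plate mean
(two-pass), which makes the factors average one; externally calibrated
reference values can be supplied when runs must be anchored to an
earlier study. Interassay CV is monitored on two further controls that
are never used for correction, so corrected and uncorrected CVs are
comparable without circularity.

## Agreement and bias statistics

`bland_altman()` reports the mean difference and limits of agreement at
exactly ±2 SD of the differences (the conventional figure-caption
definition, not 1.96). `fit_saturation()` fits the Michaelis–Menten curve
$vmax \cdot A/(km+A)$ by Levenberg–Marquardt (via \pkg{minpack.lm}) with
deterministic initialisation — $vmax_0$ the largest observed CEC, $km_0$
the concentration at half-maximum by linear interpolation — bounds
$vmax, km \ge 0$, relative RSS tolerance $10^{-8}$ and at most 500
iterations; a fit collapsing to $km \approx 0$ is flagged as the
saturated boundary rather than treated as failure. The tests check
parameter recovery on exact curves to $10^{-6}$ and agreement with an
independent 200×200 grid-search oracle.

`seeding_bias()` regresses well-level CEC on the z-scored resazurin net
ratio with a fixed intercept per sample and one common slope: the CEC
change per 1 SD of the cell-number proxy. A mixed model with random
sample effects is the textbook choice, but with a handful of samples in
triplicate the random-effect variance is weakly identified while the
estimand — the common slope — is identical; the package therefore uses
fixed-effects least squares with a t-based CI on the residual degrees of
freedom. The z-score is taken over all analyzed wells (the natural scope
when one experiment is analyzed at a time), which also makes the slope
invariant to shifting every ratio by a constant.

`camp_contrast()` is a Welch contrast of sample-mean CEC between
cAMP-treated and untreated wells; degenerate zero-variance inputs return
the point difference with a zero-width interval instead of failing.

## Resazurin cell monitoring

After the supernatant is taken, a resazurin incubation gives a 570/600 nm
absorbance ratio proportional to the number of metabolically active
cells; the ratio of a cell-free well is subtracted as blank. The net
ratio is the cell-number proxy for the seeding-bias regression, and
`normalize_to_resazurin()` rescales CEC to the plate-mean cell number for
users who want to test that normalization on their own data — on
simulated standard runs it *increases* the per-well method's interassay
CV, as expected for a method that already references each well
internally, so it is monitoring, not a correction, in the default
pipeline.

## The synthetic plate generator

Every downstream stage is testable without access to cohort sera because
`simulate_run()` generates plate exports with the error structure the
analysis assumes. Per well, in one seeded RNG stream (per-plate effects
first, then one vectorised block per quantity over wells in design
order):

1. cells are seeded lognormally around $7\times10^4$ per well
   (`seed_cells`), CV `seeding_cv` (3% default; ~30% mimics a gross
   deliberate seeding error), times any design multiplier;
2. with probability `detach_rate` (3%) a well loses part of its
   monolayer before efflux (lognormal retained fraction, mean 0.7):
   supernatant and lysate shrink together, so per-well referencing
   absorbs these events while t0 referencing sees a heavy-tailed error —
   this is what gives the two methods genuinely different rejection
   rates;
3. total label is `stain_per_cell` × cells with a small staining CV;
4. the effluxed fraction is
   $passive + b_p\, s\, (E_{max}/100)\, A/(K_m\,(c/c_0)+A)$:
   saturating in acceptor concentration $A$, with half-saturation scaled
   by the relative cell number $c/c_0$ so that raising cells at fixed
   acceptor lowers the acceptor:cell ratio and with it the per-well CEC,
   while the t0 method's fixed reference makes its CEC rise — the two
   opposite-signed seeding biases. The functional form linking cell
   number to efflux is a modelling convenience (no published form
   exists); only the direction of both biases is asserted anywhere.
   $s$ is the sample's true efflux shift and $b_p$ a per-plate
   multiplicative efflux bias (`plate_efflux_sd`), the component the
   four-control correction targets — distinct from the per-plate reader
   gain (`plate_gain_sd`), which both CEC formulas cancel;
5. t0-control wells are lysed at time zero and additionally carry a
   per-plate surrogate mismatch (`t0_mismatch_sd`, 8%): they skip the
   4-h incubation and washes, so their recovered label drifts from the
   incubated wells' true total plate by plate. This t0-specific
   plate-level error is what makes the t0 method's interassay CV
   systematically larger, and it is removed (being multiplicative) by
   the plate correction;
6. reads are signal × gain × lognormal noise (`meas_cv`) plus an
   additive background shared with unstained wells; the lysate read
   misses a `lysis_residual` fraction of the cell label (≈0.024 for
   cholic acid, ≈0.061 for sodium hydroxide — the latter inflates
   per-well CEC, reproducing the lysis-reagent direction);
7. the resazurin ratio is blank + `resazurin_per_cell` × cells × noise.

Lognormal noise everywhere keeps counts and signals positive at any CV.
All fractions are validated into [0, 1), and an efflux fraction leaving
that range aborts generation rather than clamping.

What the generator does **not** emulate: efflux kinetics over time,
cholesterol mass and esterification, lysis chemistry beyond the residual
fraction, spatial (edge) plate effects, or the absolute effect sizes of
any real cohort. Green tests therefore certify the pipeline's arithmetic,
its invariances and the direction of each mechanism — not the CVs or
biases a laboratory will observe on real sera.

## Problem sizes and reproducibility

The bundled study-scale checks use 25 plates of 20 triplicate samples
plus the full control complement (~500 samples, ~2,400 wells), a single
seeding-error plate (5 sera × 4 seeding levels × 3), a repeat-measurement
experiment of 28 sera measured on two days of two plates each, and a
five-point acceptor sweep — sizes at which every directional result is
stable across seeds while the whole suite runs in seconds. Identical
configuration and seed reproduce byte-identical exports and reports
(`write_run()`, `run_pipeline()`); grid CSVs render doubles with `%.17g`
so a file round trip is bit-exact. `scripts/acceptance.R` re-runs all of
these end to end from a single `--seed`.

## Known limitations

* Expected control values default to within-run means, so the correction
  removes relative, not absolute, plate effects; anchoring across
  studies needs externally supplied expectations.
* The rejection rule is a hard CV gate; no outlier-dropping within
  triplicates is attempted (a single aberrant replicate rejects the
  sample rather than being trimmed).
* The seeding-bias model assumes a common slope across samples; strongly
  sample-specific seeding responses would call for the mixed model the
  package deliberately avoids at these sizes.
* Passive efflux is subtracted as a plate-level constant; acceptor- or
  sample-dependent passive release is not modelled.
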