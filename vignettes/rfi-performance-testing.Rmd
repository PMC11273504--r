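---
title: "Residual feed intake evaluation: models, simulation, and test-duration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual feed intake evaluation: models, simulation, and test-duration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfitrial)
```

## The problem

Feed is the dominant cost of raising beef cattle, and animals of identical
weight and growth rate can differ substantially in how much they eat.
Residual feed intake (RFI) captures this: it is the difference between an
animal's observed dry-matter intake (DMI) and the intake predicted from its
growth rate and metabolic body size. An animal with negative RFI eats less
than expected for its performance — it is the efficient one — and because
RFI is phenotypically independent of growth and weight, selecting on it
improves efficiency without dragging mature size along.

Measuring RFI requires an individual-intake performance test: heifers are
housed with electronically keyed feeding gates, fed ad libitum for roughly
ten weeks, weighed on two consecutive days at each end of the test and
every 14 days in between, and (optionally) ultrasound-scanned for 12th-rib
backfat depth near the end of test. This package implements the complete
evaluation workflow for such tests — data editing, growth metrics, the
expected-intake regressions, efficiency classification, shortened-test
evaluation, and classification-agreement statistics — together with a
seeded simulator so that every stage is testable without access to
proprietary trial data.

## Growth metrics

Two definitions of average daily gain (ADG) are supported:

* **ADG₁** — the ordinary-least-squares slope of body weight on day of
  test, using every weigh point (including the duplicated boundary days
  −1/0 and D−1/D). Using all points extracts the most information from the
  biweekly schedule; users who want a restricted point set can subset the
  weigh data before calling `adg_by_regression()`.
* **ADG₂** — (final BW − initial BW) / days on test, where the boundary
  weights are the means of the two consecutive-day weighings and the
  denominator is the *nominal* test length (70 d), not the 71-day span of
  the weighing window.

Metabolic midweight, the classical 0.75-power scaling of maintenance
requirements, is computed from each gain definition:

MMWT = (final BW − 0.5 × days × ADG)^0.75, in kg.

MMWT₁ always pairs with ADG₁ and MMWT₂ with ADG₂. A compatibility flag
`legacy_lb_mode` evaluates the 0.75 power on the pound scale and rescales
(`(mid × 2.20462)^0.75 / 2.20462`), which reproduces the ≈ 66 scale seen in
some published summary tables rather than the ≈ 81 the kg formula yields
for a 349-kg midweight. The package defaults to the formula as written in
kg and takes no position on which scale a given historical table used —
the flag exists so either can be reproduced transparently.

## The four expected-intake models

Per-animal mean DMI over the test window (days 1..D) is regressed on gain
and metabolic midweight by OLS; the residual is the RFI:

* Model 1: DMI ~ ADG₁ + MMWT₁ (residual RFI₁)
* Model 2: DMI ~ ADG₁ + MMWT₁ + UBF (residual RFI_bf1)
* Model 3: DMI ~ ADG₂ + MMWT₂ (residual RFI₂)
* Model 4: DMI ~ ADG₂ + MMWT₂ + UBF (residual RFI_bf2)

UBF is the end-of-test ultrasound backfat depth in mm; animals without a
backfat record are dropped from Models 2/4 only, so the unadjusted and
adjusted models can legitimately have different n.

The model statements contain no contemporary-group term, so the default
`fit_scope` is `"pooled"` — one regression over all retained animals.
Because published analyses of this design are ambiguous about whether
group entered the fit (reported fractions of intake variance explained
differ between sections of the same study), `per_group` and
`group_fixed_effect` scopes are selectable; residuals sum to zero within
every fitted scope in all three.

Animals are classified within contemporary group: more than 1 group-SD of
RFI above the group mean is `high` (inefficient), more than 1 SD below is
`low`, the rest are `medium`. "More than" is read strictly, so a value
exactly at ±1 SD is `medium`. The SD is the within-group sample SD (n − 1
denominator) of the residuals. With normally distributed residuals this
yields roughly 16% / 68% / 16% classes. `class_summary()` reports
*unadjusted* arithmetic class means ± SEM — not least-squares means
adjusted for farm, sire or trial, which are outside this package's scope —
plus the percent intake excess of the high class over the low class.

## Test-duration analysis

To ask whether a 70-day test can be shortened, the trial is truncated at
each candidate duration d ∈ {14, 28, 42, 56}: mean DMI is recomputed over
days 1..d, ADG₁ from the weigh points at or before d, ADG₂ from the
day-d weight, and the RFI models are *refit* on the truncated summaries
(truncated RFI is the residual of that duration's own model, not a
truncation of the full-test residuals). Full-test values are then
regressed on truncated values and Pearson/Spearman correlations computed;
at d = 70 every statistic equals 1 by construction. Backfat never enters
the truncated models because ultrasound is collected only at the end of
the full test.

Two numerical details are worth knowing:

* A mid-test truncation has no consecutive-day weighing pair, so the
  truncated "final BW" is the single day-d weight (at d = 70 the usual
  69/70 average is used, which makes the identity truncation exact).
* Because initial BW is a two-day average centred half a day before day
  0, the truncated ADG₂ of a noise-free animal equals the true gain times
  (d + 0.5)/d rather than exactly. This half-day endpoint bias is shared
  by all animals, so it shifts the regression slope (to d/(d + 0.5) at
  zero noise) but not the correlations. At the full test length the same
  offset in the final average cancels it exactly.

The t-approximation is used for all correlation p-values, including
Spearman (computed as the Pearson correlation of midranks).

## Agreement statistics

Model pairs are compared three ways: correlations of the residuals,
regression of one residual set on the other with a t-based slope CI and a
flag for whether the CI contains 1 (model equivalence on the identity
line), and chance-corrected agreement of the classifications.

Cohen's kappa is computed from the 3×3 confusion matrix over the ordered
categories low < medium < high, both unweighted and weighted. Weighted
kappa defaults to linear (Cicchetti–Allen) weights
w_ij = 1 − |i − j|/(C − 1) — the default of the SAS procedure
traditionally used for this analysis — with quadratic weights available
as an option; because published reports often do not say which variant
they used, both the unweighted and weighted values are always returned.
Standard errors use the Fleiss–Cohen–Everitt asymptotic variance (the
delta-method variance of the multinomial confusion proportions), with the
null-hypothesis form used for the z-test of H₀: κ = 0 and the non-null
form for the 95% CI κ ± 1.96·SE. The implementation is verified in the
test suite against a numeric delta-method gradient and against
Monte-Carlo spread under independence. Agreement bands follow the
conventional cut-offs: κ < 0.4 low, 0.40–0.75 (closed) fair-to-good,
> 0.75 high.

## Data editing (QC)

Three edits are applied, in this order, by `run_qc()`:

1. **Incomplete feed records** — an animal must have a DMI value for
   every day 1..D.
2. **Age window** — at least 240 d old at the start of test and no older
   than 390 d at its completion (both inclusive, whole-day arithmetic).
3. **Intake screen** — total test intake within ±4 SD of the
   contemporary-group mean, with the group statistics computed *including*
   the candidate and recomputed on the survivors of the first two edits.

The inclusive screen has a small-group ceiling worth understanding: with
the candidate included, the largest attainable |z| in a group of n is
(n − 1)/√n, so a lone outlier in a group of 12 (max |z| = 3.18) can never
breach the 4-SD threshold, while the same outlier in a group of 46 is
excluded at |z| = 6.6. This is a property of the screen as defined, not a
bug; the test suite demonstrates both sides.

## The simulator

`generate_trial()` draws, per heifer: age at start of test (normal,
clamped into the 240–390-day window), day-0 body weight and true ADG from
its contemporary-group distributions, an animal-level efficiency residual
(true RFI) ~ N(0, σ_RFI), and a backfat depth constructed bivariate-
normally with correlation `ubf_rfi_corr` to the efficiency residual
(ultrasound is a single end-of-test scan, not a growth curve). Latent
mean DMI follows the same linear structure the analysis fits — intercept
+ 1.8·ADG + 0.105·MMWT + 0.05·UBF + RFI — so recovery of the generating
residual by the fitted models is a meaningful end-to-end check. Daily
intakes add N(0, σ_daily) noise; weights follow the line
BW(t) = BW₀ + ADG·t plus N(0, σ_weigh) at each weighing on the schedule
{−1, 0, 14, 28, 42, 56, 69, 70}. Feed intake is emitted directly as kg
dry matter per day; offered/refused accounting and ration composition are
not simulated because the analysis consumes DMI only.

The default configuration recreates a 186-heifer, seven-group, two-farm
evaluation (group sizes 20/46/22/23/22/12/41) with group-level weight and
gain distributions typical of growing Brangus replacement heifers.
Defaults that the emulated design does not pin down were chosen once as
field-realistic values: σ_daily = 2.5 kg/d (ad-libitum day-to-day intake
swings of 20–25%), σ_weigh = 4 kg (gut-fill variation at ~350 kg body
weight), backfat 7.7 ± 2.5 mm with a weak 0.2 coupling to efficiency
(backfat–efficiency relationships in the literature are weak and
inconsistent), and age 280 ± 15 d. With σ_RFI = 0.95 kg/d the base model
attains R² ≈ 0.51 on the default seed, inside the 0.40–0.65 band typical
of these trials.

Ground truth bookkeeping: `true_initial_bw` is recorded as the expected
*measured* initial weight — the day −1/0 mean of the noise-free line,
BW₀ − ADG/2 — so zero-noise endpoint averages recover it exactly.

Reproducibility protocol: one root seed; each heifer's draws come from a
substream seeded deterministically by (root seed, animal index), so
appending a group to the configuration never perturbs earlier animals,
and identical (config, seed) pairs reproduce the CSVs byte-for-byte.

### What the simulator does and does not emulate

It reproduces the statistical skeleton that the analysis machinery sees:
group structure, between-animal spread in gain, size and efficiency, noisy
daily intake, noisy biweekly weights, and a weak backfat–efficiency link.
It does not emulate serially correlated intake (weather, estrus, health
events), growth-curve nonlinearity, pen/social effects, gate-training
failure, or missing data — so passing recovery tests here demonstrates
the *machinery* is correct, not that real trials will show the same
correlation levels. In particular the simulator's day-to-day intake noise
is white, which makes short-window intake means slightly better predictors
of the 70-d mean than serially correlated real data would be.

## Problem sizes and runtime

The test suite and worked examples use the 186-animal default cohort (one
seed) for cohort-level checks, 20 seeds for the duration-pattern
properties, and n = 10,000 single-group draws for distributional checks
of the classifier and the backfat coupling; the whole suite runs in well
under a minute on one core.

## A worked run

```{r example, eval = FALSE}
cfg <- run_config(out_dir = "rfi_run", seed = 1)
bundle <- run_pipeline(cfg)
make_report(bundle)

# duration analysis alone
tr <- generate_trial(default_sim_config(), seed = 1)
duration_table(tr$heifers, tr$weights, tr$intake,
               metrics = c("DMI", "ADG1", "RFI1"))
```

## Known limitations

* Class summaries are unadjusted means; fixed-effect adjustment (farm,
  sire, trial) is deliberately out of scope.
* The intake screen follows the inclusive-statistics reading; leave-one-
  out screening would behave differently in small groups.
* Kappa CIs are asymptotic; they can exceed 1 for near-perfect agreement
  on small n.
* The simulator's white intake noise slightly flatters short test
  durations (see above); qualitative duration patterns (intake stabilises
  early, gain is the limiting trait) are robust to this, absolute
  correlation levels are not.
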