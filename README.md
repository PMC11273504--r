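# rfitrial

Residual-feed-intake (RFI) evaluation for individual-intake performance
tests of growing beef cattle, with a seeded feed-trial simulator.

## Who this is for

Animal scientists and performance-test managers who run (or study)
individual-intake trials — heifers on electronically keyed feeding gates
for ~70 days, weighed biweekly, optionally ultrasound-scanned for
12th-rib backfat — and need the standard downstream analysis: data edits,
growth metrics, expected-intake models, efficiency classification,
shortened-test evaluation, and agreement between alternative model
rankings. Because raw trial data are usually proprietary, the package
ships a simulator that reproduces the statistical structure of a
multi-group trial, so the whole pipeline is testable end to end.

## The model

RFI is the residual of an ordinary-least-squares regression of mean daily
dry-matter intake on average daily gain (ADG) and metabolic midweight
(MMWT):

```
DMI_i = β0 + β1·ADG_i + β2·MMWT_i (+ β3·UBF_i) + e_i,      e_i = RFI_i
```

with `MMWT = (final BW − 0.5·days·ADG)^0.75` in kg and UBF the optional
ultrasound backfat depth (mm). Gain enters either as the regression slope
of weight on day (ADG₁, with MMWT₁) or as the endpoint difference divided
by days on test (ADG₂, with MMWT₂), giving four models: 1 (ADG₁), 2
(ADG₁ + UBF), 3 (ADG₂), 4 (ADG₂ + UBF). Animals more than 1 SD of RFI
above their contemporary-group mean are classified `high` (inefficient),
more than 1 SD below `low` (efficient), otherwise `medium`. Shortened
tests are evaluated by regressing full-test values on values recomputed
from truncated windows (14/28/42/56 d), and model agreement by Pearson /
Spearman correlations, slope-equivalence regression, and (weighted)
Cohen's kappa on the classifications.

## Worked example

```r
library(rfitrial)

tr  <- generate_trial(default_sim_config(), seed = 1)   # 186 heifers, 7 groups
tab <- growth_summary_table(tr$heifers, tr$weights, tr$intake)
fits <- compute_rfi_models(tab)
fits$RFI_1
#> Expected-DMI model (regression ADG, scope pooled), n = 186
#> R-squared: pooled = 0.510

cls <- classify_rfi(fits$RFI_1)
table(cls$classes)
#>    low medium   high
#>     29    124     33

cs <- class_summary(tab, cls)
cs$pct_dmi_excess_high_vs_low
#> [1] 27      # high-RFI heifers eat 27% more feed/day for the same gain

duration_table(tr$heifers, tr$weights, tr$intake,
               metrics = c("DMI", "ADG1", "RFI1"))[, 1:5]
#>    metric duration_d slope r_squared pearson
#> 1     DMI         14  0.87      0.84    0.91
#> 2    ADG1         14  0.33      0.29    0.54
#> ...
#> 10    DMI         56  0.97      0.99    0.99
#> 11   ADG1         56  0.97      0.95    0.97
#> 12   RFI1         56  0.95      0.95    0.98

cohen_kappa(cls$classes, classify_rfi(fits$RFI_2)$classes)
#> Cohen's kappa: 0.989 (SE 0.011, 95% CI 0.968-1.010) -- high agreement
#> Weighted kappa (linear): 0.990 (SE 0.010, 95% CI 0.972-1.009), p = 5.1e-78
```

Reading the numbers: the base model explains ~51% of intake variance;
intake measured over only the first 56 days correlates 0.99 with the
70-day value (and the 56-d RFI ranking correlates 0.98 with the full-test
ranking), while 14-day gain correlates just 0.54 — gain, not intake, is
what limits how short a test can be. The two gain definitions produce
nearly interchangeable RFI rankings (κ ≈ 0.99).

Or run everything at once and get a report bundle on disk
(`qc_report.csv`, `growth_summary.csv`, `rfi_results.csv`,
`model_fits.json`, `duration_table.csv`, `agreement_report.json`,
`run_log.txt`):

```r
bundle <- run_pipeline(run_config(out_dir = "rfi_run", seed = 1))
make_report(bundle)          # formatted group / class / duration tables
verify_pipeline(run_config(out_dir = "rfi_run", seed = 1))  # byte-level re-check
```

See `vignettes/rfi-performance-testing.Rmd` for the full account of the
models, the simulator's assumptions, and numerical edge cases.

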