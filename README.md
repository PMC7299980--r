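# cesmr

Quantitative analysis of breast-lesion enhancement on contrast-enhanced
spectral mammography (CESM), for radiology researchers evaluating whether
enhancement *intensity* and two-timepoint enhancement *kinetics* can help
separate benign from malignant lesions.

CESM acquires the two standard mammographic projections (CC and MLO)
sequentially after iodinated contrast, so the pair of subtraction images
samples the lesion's kinetics at two timepoints. `cesmr` implements the
whole quantitative layer on top of that:

* **Intensity.** Per projection, the contrast-to-noise ratio
  `CNR = (Sa − Sb) / Sb`, with `Sa` the maximum pixel value in the lesion
  ROI and `Sb` the mean of a background ROI; negative ratios clamp to 0
  (darker than background is non-enhancement). Projections are ordered by
  acquisition time into CNR₁ (former) and CNR₂ (latter).
* **Kinetics.** The relative signal difference
  `RSD = 100 · (CNR₂ − CNR₁) / CNR₁` classifies each lesion as
  *ascending* (RSD > 10%), *steady* (|RSD| ≤ 10%), *descending*
  (RSD < −10%) or *none* (non-enhanced, scored zero) — the CESM analogue
  of the DCE-MRI persistent / plateau / washout time-intensity curve
  (TIC) types.
* **Statistics.** Five-number group summaries, Wilcoxon / Mann–Whitney /
  Kruskal–Wallis tests with Bonferroni correction, empirical ROC curves
  with Youden cut-offs and DeLong confidence intervals, the DeLong paired
  AUC comparison between projections, detection cross-tabs, and Cohen's
  kappa agreement between CESM patterns and MRI TIC categories.
* **Synthetic data.** A cohort generator calibrated to a published
  145-lesion study (102 benign / 17 non-infiltrating / 26 infiltrating)
  via zero-inflated piecewise-linear quantile samplers, and phantom
  subtraction-image pairs with analytically known CNR, so the entire
  pipeline is testable without clinical data.

Everything is tibble-in / tibble-out and chains with the pipe.

## Worked example

```r
library(cesmr)

report <- run_analysis(cohort_config(seed = 11))
report
#> <cesm_report> 145 lesions (102 benign / 43 malignant)
#>   AUC former 0.921 vs latter 0.880 (DeLong p = 0.004145)
#>   CESM-MRI coincidence 82.1%, kappa = 0.735 (n = 28)

report$pattern_table
#> # A tibble: 8 × 4
#>   group     pattern        n percent
#>   <chr>     <chr>      <int>   <dbl>
#> 1 benign    ascending     28   27.5
#> 2 benign    steady         4    3.92
#> 3 benign    descending     3    2.94
#> 4 benign    none          67   65.7
#> 5 malignant ascending      6   14.0
#> 6 malignant steady         7   16.3
#> 7 malignant descending    30   69.8
#> 8 malignant none           0    0

glance(report$roc$cnr1)
#> # A tibble: 1 × 10
#>     auc auc_se ci_lower ci_upper cutoff sensitivity specificity youden ...
#> 1 0.921 0.0214    0.879    0.963   1.79           1       0.775  0.775

report$roc$comparison
#> # A tibble: 1 × 6
#>    auc1  auc2 difference     se     z p_value
#> 1 0.921 0.880     0.0413 0.0144  2.87 0.00415
```

Reading the output: on this simulated cohort the former projection's CNR
discriminates benign from malignant lesions with AUC 0.921, significantly
better than the latter projection's 0.880 (DeLong p = 0.004) — early-phase
intensity carries more diagnostic signal. Malignant lesions concentrate in
the descending (washout-like) pattern, benign lesions in the non-enhanced
and ascending patterns, and the CESM patterns agree moderately-to-well
with the simulated MRI TIC labels. `write_report(report, dir)` writes each
table as CSV plus a full-precision `report.json` twin;
`autoplot(report$roc$cnr1)` and `plot_pattern_distribution(report)` draw
the standard figures. A command-line wrapper with `simulate`, `measure`,
`score`, `analyze` and `run-all` subcommands ships in
`inst/scripts/cesm-cli.R`.

Individual stages are available directly: `quantile_spec()` /
`sample_cnr_pairs()` (calibrated samplers), `render_phantom_pair()` /
`measure_roi()` / `order_views()` (image-level measurement),
`compute_rsd()` / `classify_pattern()` / `score_cohort()` (kinetics), and
the statistics layer (`roc_analysis()`, `compare_auc_paired()`,
`cohen_kappa()`, `contingency_test()`, `detection_crosstab()`, ...).

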