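# redoxflim

Synthetic autofluorescence metabolic imaging of brain tumors: a calibrated
cohort simulator coupled to the full analysis pipeline — spectral redox
metrics, frequency-domain flavin lifetimes, nonparametric cohort
statistics, and multi-class tumor-entity classification.

## The problem

Label-free optical imaging reads tissue metabolism from endogenous
fluorophores: free NAD(P)H (462 nm emission) rises with glycolysis, FAD
(530 nm) with oxidative phosphorylation, and protein-bound FMN (495 nm,
~10× the FAD quantum yield, ~4.7 ns lifetime) accumulates as tumors shift
toward aerobic glycolysis. Three metrics summarize a measurement:

* optical redox ratio `RR = FAD / (NAD(P)H + FAD)`, from band integrals
  over 430–475 nm and 520–600 nm of the emission spectrum;
* `R_flavin = I495 / I530`, the protein-bound FMN to FAD peak ratio;
* the flavin fluorescence lifetime (500–580 nm band), estimated by
  frequency-domain FLIM (`τ_φ = tan φ / 2πf`).

A glycolytic shift lowers `RR` and raises `R_flavin` and the lifetime;
the three features separate tumor entities in a surgical cohort of five
groups (control, low-/high-grade glioma, meningioma, metastasis;
16/71/117/64/93 data points). The underlying patient data are not public,
so this package generates a synthetic cohort calibrated to the published
group quartiles, average-spectrum peak anchors and pooled
R_flavin-vs-RR correlation, and runs the complete published analysis
protocol on it. It is aimed at researchers who want a tested, fully
reproducible reference implementation of the metrics, the statistics and
the classification protocol, with a generator standing in for the
unavailable data.

## Worked example

```r
library(redoxflim)

presets <- default_presets()          # calibrates marginals, spectra, coupling
#> <cohort_presets: 5 groups, 361 data points, coupling 0.885, pooled r -0.870>

cohort <- generate_cohort(presets, seed = 1)
table(cohort$group)
#> CTL LGG HGG MNG MET
#>  16  71 117  64  93

subset(hypothesis_battery(cohort), metric == "tau_ns")
#>    group metric   n median  q25  q75  p_value stars significant
#> 11   CTL tau_ns  16   1.38 1.35 1.68       NA             FALSE
#> 12   LGG tau_ns  71   2.77 2.20 2.99 1.05e-08    **        TRUE
#> 13   HGG tau_ns 117   2.34 2.10 2.69 1.44e-09    **        TRUE
#> 14   MNG tau_ns  64   3.83 3.11 4.37 8.09e-10    **        TRUE
#> 15   MET tau_ns  93   2.41 2.16 2.75 8.59e-09    **        TRUE

metric_regression(cohort$r_flavin, cohort$redox_ratio)$pearson_r
#> [1] -0.8656399
```

Every tumor group shows a significantly longer flavin lifetime than the
control group (one-sided Mann-Whitney-U against CTL; stars `*`/`**` at
p < 0.005 / 1e-5), and the pooled correlation between the FMN/FAD ratio
and the redox ratio is strongly negative — more glycolytic tissue carries
more protein-bound FMN.

The classification protocol (SMOTE-balanced training folds, stratified
5-fold CV repeated 50 times, RBF support-vector model on the three
features) aggregates all 250 validations:

```r
ft <- feature_table(cohort)
preds <- repeated_stratified_cv(ft$features, ft$labels, ft$ids,
                                model = "svc", n_repeats = 50, seed = 42)
aggregate_confusion(preds)
#> Aggregated confusion matrix (rows = truth, 18050 predictions)
#>     CTL  LGG  HGG  MNG  MET  SE%  SP%
#> CTL 699    0   51    0   50 87.4 94.4
#> LGG   0 3145  319   66   20 88.6 84.1
#> HGG 660 1653 2960   70  507 50.6 89.4
#> MNG 101  299   59 2269  472 70.9 96.6
#> MET 213  348  865  365 2859 61.5 92.2
```

Rows are true classes, columns predictions; `SE`/`SP` are one-vs-rest
sensitivity and specificity per class. Non-tumorous tissue and gliomas
are detected reliably; high-grade gliomas and metastases overlap — the
same confusion structure the three metrics produce on real tissue.

A full artifact tree (cohort CSV, spectra TSVs, FLIM TIFFs, battery and
confusion tables, plot-ready JSON) can be produced with
`cmd_simulate()` / `cmd_analyze()` / `cmd_report()` or the thin CLI
wrapper:

```sh
Rscript inst/cli/redoxflim.R all --seed 1 --out run1
```

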