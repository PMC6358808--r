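# plsval

Partition-validated paired PLS-DA for matched-cohort metabolomics.

## The problem

Targeted metabolomic panels (e.g. Biocrates p180-style kits quantifying 188
metabolites across six biochemical families) are increasingly used to search
for biomarkers in small, matched case-control cohorts — for instance
patients who do or do not undergo left-ventricular remodeling (LVR) after an
ST-elevation myocardial infarction, matched one-to-one on clinical
covariates. Two statistical hazards dominate at this scale:

* **Quantitation accuracy.** Measurements below the lower (LLOQ) or above
  the upper (ULOQ) limit of quantitation are unreliable; metabolites with
  more than 20% of such values must be excluded before analysis.
* **Overfitting of discriminant models.** PLS-DA on dozens of samples and
  a hundred-plus variables separates almost anything in-sample. A single
  random train/test split is itself a lottery at n = 64, so a model's
  predictive claim should be evaluated over *every* admissible split.

`plsval` implements the full workflow: LLOQ/ULOQ filtering,
Shapiro-Wilk-gated paired univariate testing with Benjamini–Hochberg
correction, multilevel (within-pair) NIPALS PCA with Hotelling T² outlier
screening, and the exhaustive-partition validation engine for paired PLS-DA.
A synthetic matched-cohort generator (effect and null modes) makes the whole
pipeline testable without patient data.

## The validation engine

With 32 matched pairs, allocating 22 pairs (~2/3 of samples) to training and
10 pairs to testing admits C(32,22) = 64,512,240 distinct models. The engine
enumerates them lexicographically by combinadic unranking (no matrix of
combinations is ever materialized), thins the enumeration systematically —
every 310th rank gives 208,104 models — and, for each partition:

1. applies unit-variance scaling fitted on the training block only,
2. fits a NIPALS PLS1 model to the dummy-coded class label,
3. predicts the held-out test samples and computes the test-set AUROC,
4. computes the tail probability of that AUROC under the **mean model**
   (random prediction of patient status).

Because the multilevel transform makes test predictions antisymmetric
within each matched pair, the engine assesses significance against the exact
sign-flip (Walsh-average count) null rather than the two-sample
Mann–Whitney null — see the methods vignette for the derivation. Under a
true null each 5% tail then contributes 5% of models, 10% in total.

The sweep is judged by medians: variable selection (median VIP > 1) is
performed only if the median AUROC is at least 0.8 and the median p-value at
most 0.05; otherwise the verdict is that the panel does not discriminate.

## Worked example

```r
library(plsval)

sim  <- generate_cohort(cohort_config(seed = 42))   # 32 matched pairs
filt <- filter_metabolites(flag_out_of_range(sim$matrix))
print(filt$report)
#> Quantitation filter (> 20% out-of-range dropped): 142 of 188 metabolites retained (75.5%)
#>   acylcarnitines              12 /  40
#>   amino acids                 21 /  21
#>   biogenic amines             12 /  21
#>   hexoses                      1 /   1
#>   lysophosphatidylcholines    12 /  14
#>   phosphatidylcholines        70 /  76
#>   sphingomyelins              14 /  15

uni <- compare_groups(filt$matrix, sim$cohort$group, pair = sim$cohort$pair_id)
#> Univariate paired comparison, 142 variables (LVR vs noLVR), BH-adjusted
#>   significant at adjusted p <= 0.05: 2
#>        variable mean_LVR sd_LVR mean_noLVR sd_noLVR                 test    p_raw   p_adj
#>  lysoPC a C17:0    1.001 0.2688      1.460   0.4395        paired t-test 1.69e-06 0.00024
#>     PC aa C40:6   22.349 4.5159     27.200   4.8865        paired t-test 1.15e-04 0.00820
#>  ...

plan <- partition_plan(max_models = 2000)           # thinned 22/10 sweep
v <- run_validation(filt$matrix, sim$cohort$pair_id, sim$cohort$group, plan)
print(v)
#> Partition validation: 2,000 models
#>   AUROC: mean 0.704, median 0.720;  median p 0.126
#>   significantly different from the mean model: 25.0% (better 25.0%, worse 0.0%) at per-tail alpha 0.05
#>   decision: not satisfactory (need median AUROC >= 0.80 and median p <= 0.05); no variable selection
```

The reading: the simulated effect metabolites separate the groups in
univariate analysis (two survive Benjamini–Hochberg at this seed), the
partition sweep finds predictive capability above chance (median AUROC
0.72, a quarter of models significantly better than the mean model), but the
panel does not reach the 0.8/0.05 decision cutoffs, so no VIP selection is
made — the same conservative verdict mechanism that protects against
overfitted biomarker claims on real cohorts.

The full pipeline — generation, filtering, univariate tables, PCA screen,
validation, JSON + text report — runs as one call:

```r
run_pipeline(run_config(mode = "synthetic-effect", out_dir = "run1", seed = 42))
```

or from a shell via the thin CLI (`inst/scripts/plsval-cli.R`) with
subcommands `simulate`, `qc`, `univariate`, `pca`, `validate`, `all`; the
default caps validation at 5,000 models, `--full` runs the complete
systematic sweep (208,104 models, tens of minutes on one CPU).

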