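---
title: "Methods: partition-validated paired PLS-DA for matched metabolomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partition-validated paired PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsval)
```

## Scope and model of the data

`plsval` analyzes a targeted metabolomic panel measured on a matched
case-control cohort: $n$ pairs of subjects, one case (e.g. a patient with
post-infarction left-ventricular remodeling, "LVR") and one matched control
per pair, and a samples $\times$ metabolites concentration matrix in
µmol/L. The package covers four stages — quantitation filtering, paired
univariate testing, latent-variable screening and discriminant-model
validation — plus a synthetic-cohort generator that emulates the data
structure those stages assume.

## Quantitation filter

Panel kits report every concentration together with lower and upper limits
of quantitation (LLOQ/ULOQ). A measurement strictly below the LLOQ or
strictly above the ULOQ is deemed inaccurate; a value exactly at a limit
counts as measured. A metabolite is excluded when **more than** 20% of its
values are out of range ("more than" is read literally: exactly 20% is
kept), and missing cells count as inaccurate. Values are never imputed or
truncated — the filter consumes the censor flags, not the values — because
kit exports report flagged values as-is and downstream rank-based methods
tolerate them once the 20% rule holds. The filter is idempotent and
per-metabolite, hence invariant to column order.

## Univariate stage

Each variable is compared between groups with a normality-gated test
choice: Shapiro–Wilk at $\alpha = 0.05$ on the within-pair differences
(paired mode) or on each group (unpaired mode) decides between the
parametric and the rank test. Paired data use the paired $t$-test or the
Wilcoxon signed-rank test (exact distribution when $n \le 25$ and no
ties/zeros, normal approximation with continuity correction otherwise);
unpaired data use Welch's $t$-test — chosen over the pooled-variance
Student test because equal variances cannot be assumed between clinical
groups; a flag restores the pooled form — or the Mann–Whitney test.
Constant input, for which Shapiro–Wilk is undefined, falls to the rank
branch with a warning; identical groups return $p = 1$ rather than an
error. Raw p-values from one call form a single Benjamini–Hochberg family
(metabolites and routine biomarkers are adjusted separately, mirroring
their separate reporting); significance means adjusted $p \le 0.05$.

One known ambiguity: with all routine biomarkers adjusted as one family of
eight, a raw $p = 0.020$ does not survive the step-up, so published claims
that such a marker "remains significant after correction" imply a different
family choice. The adjustment family is therefore left to the caller.

## Paired (multilevel) latent-variable analysis

"Paired" PCA and PLS-DA are implemented as the multilevel decomposition:
every row is replaced by its deviation from its pair mean, so for a pair
$(a, b)$ the members become $\pm(a-b)/2$ and all between-pair variation is
removed before the standard algorithm runs. This is the established
multilevel variant in the metabolomics ecosystem; since the alternative
reading (plain PCA/PLS-DA with pair-respecting partitioning only) cannot be
ruled out, `paired = FALSE` disables the transform everywhere.

PCA and PLS-DA are computed by NIPALS, one component at a time. The PCA
convergence criterion is the relative change of the score vector,
$\lVert t_{new} - t \rVert / \lVert t_{new} \rVert \le 10^{-12}$, with at
most 1000 iterations per component (non-convergence is an error naming the
component); this tolerance keeps components equal to the singular-value
decomposition to well below $10^{-8}$, which the test suite asserts on
instances up to $20 \times 20$. Component signs follow the convention that
the largest-magnitude loading element is positive. Sample outliers are
screened on the score plot by Hotelling's $T^2$ with the
$\frac{a(n-1)}{n-a} F_{a,\,n-a}$ control limit at the 0.95 level.

PLS-DA is NIPALS PLS1 on the dummy-coded label $y \in \{0, 1\}$, centered
before fitting: per component the weight vector is the normalized
covariance direction $X^\top y$, scores $t = Xw$, and both blocks are
deflated by the x-loadings. Predictors are unit-variance scaled
($n-1$ denominator) with statistics fitted **on the training partition
only** and re-applied, never refit, to test samples; whole-matrix scaling
(the leaky variant some workflows use) is available by scaling before the
call. The default of 2 components reflects the screening character of the
sweep (the first component carries the covariance direction, the second
absorbs the dominant orthogonal structure); it is configurable everywhere.
Variable importance in projection is
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{aj}^2 / \sum_a \mathrm{SSY}_a}$
with $\mathrm{SSY}_a = q_a^2 t_a^\top t_a$ the y-variance explained by
component $a$; $\operatorname{mean}(\mathrm{VIP}^2) = 1$ identically, so
"important" conventionally means $\mathrm{VIP} > 1$.

## The partition-validation engine

A single random train/test split of 32 pairs is one draw from
$\binom{32}{22} = 64{,}512{,}240$ admissible splits, and at this sample
size the draw matters. The engine therefore treats the split as the unit of
replication: partitions are enumerated lexicographically **at pair level**
(both members of a pair stay on the same side, which also keeps the class
split balanced: 22 training pairs = 44 samples, 10 test pairs = 10 cases +
10 controls) and sampled systematically — every 310th rank yields 208,104
models; ranks are materialized on demand by combinadic unranking in $O(n)$
time, never as a combination matrix. Counts are exact below $2^{53}$;
larger designs raise an error rather than rounding silently.

Each evaluated partition yields the test-set AUROC (rank-based, midrank
ties) and its tail probability under the *mean model*, the null classifier
that predicts status at random.

### The correct null for paired predictions

For a linear model fitted to within-pair transformed data, the predicted
scores of the two members of a test pair are exactly antisymmetric about a
common constant: if the case of pair $i$ scores $c + e_i$, its control
scores $c - e_i$. The AUROC numerator over the $n \times n$ case-control
comparisons is then

$$V = \#\{(i,j) : e_i + e_j > 0\},$$

the number of positive Walsh sums counted over ordered pairs including
$i = j$. Writing $W^+$ for the number of positive Walsh averages over
$i \le j$ — which is the Wilcoxon signed-rank statistic — and $P_0$ for the
number of positive $e_i$, $V = 2W^+ - P_0$. Under the null the $e_i$ are
independent and symmetric about zero, so the law of $V$ is distribution-free
over the $2^n$ equiprobable sign patterns and can be enumerated exactly
(done for $n \le 14$, cached; beyond that a normal approximation with mean
$n^2/2$, variance $n(n+1)(2n+1)/6 + n/4 - n(n+1)/2$ and continuity
correction).

This null is substantially wider than the two-sample Mann–Whitney null
(AUROC standard deviation 0.182 vs 0.132 at $n = 10$ test pairs): applying
the two-sample null to paired predictions overstates significance by half
again. `run_validation(paired = TRUE)` therefore uses the paired null;
`auroc_pvalue()` retains the classical Mann–Whitney form (exact for
$n_+ n_- \le 400$) for unpaired designs.

### One-sided tail probabilities and the 10% accounting

The per-model `p_value` is the one-sided tail probability in the observed
direction: the probability that the mean model does at least as well
(AUROC above 0.5) or at least as poorly (below 0.5) as the model at hand.
A model is *significantly better* when its upper-tail probability is
$\le \alpha$ and *significantly worse* symmetrically, so under a true null
each tail contributes $\approx 5\%$ of models and $\approx 10\%$ differ
from the mean model in total — the accounting against which an observed
fraction should be compared. (A two-sided convention would halve these
fractions; both tail probabilities are computed, and the two-sided value
is available from `auroc_pvalue*(…, alternative = "two.sided")`.) Exact
discreteness makes the realized per-tail level 0.0479 rather than 0.05 at
$n = 10$ test pairs.

### Decision rule and variable selection

Because neither the AUROCs nor the p-values of the sweep are normally
distributed, medians summarize them. The panel's discriminative performance
is *satisfactory* only if the median AUROC is $\ge 0.8$ and the median
p-value $\le 0.05$; only then are variables selected, as those whose
**median VIP across all evaluated models** exceeds 1 (the per-model VIP > 1
convention aggregated by the median, consistent with the engine's use of
medians elsewhere; the aggregation across models is a package choice, since
per-model selection would produce 208,104 different sets). Loading signs
are retained in the fitted models as direction indicators, but the decision
uses VIP only.

### What a single cohort can and cannot show

All models of one sweep share one dataset: their AUROCs are strongly
correlated, and the *fraction* of significant models on a single cohort is
itself a random quantity with a spread of tens of percentage points around
the 10% null expectation — a null cohort can legitimately print anything
from a few percent to several tens of percent. The engine is calibrated in
the marginal sense: averaged over replicate cohorts the significant
fraction approaches 10% (upper tail 5%), which is what
`scripts/acceptance.R` measures by spreading 2,000 models over 500
independent null cohorts. The practical corollary for real studies, where
only one cohort exists: an observed fraction near 10–11% is consistent
with no signal, but the comparison carries wide, not binomial, error bars.

## The synthetic-cohort generator

The generator emulates a p180-like panel measured on matched pairs:

* **Panel:** 188 metabolites in the acylcarnitine (40), amino acid (21),
  biogenic amine (21), lysophosphatidylcholine (14), phosphatidylcholine
  (76), sphingomyelin (15) and hexose (1) families, of which
  12 + 21 + 12 + 12 + 70 + 14 + 1 = 142 are designed to pass the 20%
  quantitation filter.
* **Distributions:** concentrations are log-normal, moment-matched to the
  configured arithmetic mean ± sd — strictly positive and right-skewed, as
  serum panels are; only means and sds are ever specified, so the skewness
  and tail behaviour of real panels beyond log-normality are *not*
  emulated.
* **Effects:** five metabolites carry group differences in effect mode
  (SDMA 0.57 ± 0.15 vs 0.52 ± 0.07 µmol/L; SM C20:2 0.29 ± 0.07 vs
  0.25 ± 0.05; lysoPC a C17:0 1.13 ± 0.30 vs 1.37 ± 0.46; PC aa C40:6
  23.26 ± 6.08 vs 25.96 ± 6.48; PC aa C42:3 0.47 ± 0.10 vs 0.52 ± 0.11);
  null mode gives every variable its control distribution in both groups,
  making labels exchangeable. Routine biomarkers (CK peak, CRP, leukocyte
  and neutrophil counts, NT-proBNP, creatinine) are generated the same way.
* **Matching:** a shared pair-level intercept on the standardized log scale
  induces a within-pair correlation of 0.3 by default — matched cohorts are
  more alike within pairs than between, but no study quantifies the
  strength, so the value is a field-plausible choice and configurable in
  `[0, 1)`. The marginal distribution of each metabolite is unaffected.
* **Censoring:** each metabolite's LLOQ is placed at the quantile of its
  control distribution matching the configured out-of-range probability
  (0.02 for retained, 0.6 for designed-to-fail analytes; censoring acts
  from below, as for low-abundance analytes), so the 142/188 retention is
  reproduced with near-certainty at any seed while out-of-range fractions
  stay binomially calibrated. Flagged cells keep their numeric value.
* **Covariates:** age and sex are pair-level (matched); hypertension
  prevalence differs by group (56.3% vs 25.0%) in effect mode. Covariates
  carry no metabolite coupling.
* **Antithetic mode:** `generate_cohort(…, antithetic = TRUE)` sign-flips
  all standardized normal deviates while consuming the identical random
  stream; a seed generated once normally and once antithetically gives a
  negatively correlated cohort pair with the same marginal law, the
  standard variance-reduction device used by the mean-recovery tests.

What passing tests on these cohorts do **not** show: robustness to batch
and plate effects, non-log-normal tails, missingness mechanisms, or
covariate-metabolite confounding, none of which are simulated.

## Problem sizes and numerical choices

The test suite and the acceptance script run thinned sweeps — 2,000 models
for calibration checks, tens of models for decision-rule and planted-effect
checks — which keeps the default suite under a minute while exercising the
identical code path as the full sweep; one test evaluates partitions from
both ends and the middle of the full 208,104-rank plan and bounds the
per-model cost, demonstrating that the complete single-CPU sweep is a
matter of tens of minutes. Further numerical conventions: standard deviations use the $n-1$
denominator; zero-variance columns are dropped with a warning before
scaling; ties in AUROC take midranks; the Wilcoxon exact/approximate
switch is as described above; all validation results are deterministic
functions of data and plan, so reruns are bit-identical.

## Known limitations

* The paired AUROC null assumes exactly antisymmetric test scores, which
  holds for linear predictors on within-pair transformed data; a future
  nonlinear back end would need a permutation null instead.
* With weak, sparse effects at $n = 32$ pairs the sweep can sit
  *below* AUROC 0.5 for a given cohort (small-sample anti-learning);
  planted strong effects validate cleanly. The decision rule is one-sided
  by construction and treats such cohorts as non-discriminating.
* Biomarker adjustment families, the paired/plain analysis switch, the
  component count and all cutoffs (0.20, 0.8, 0.05, VIP 1) are parameters,
  not constants of nature; defaults follow the workflow the package
  implements.
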