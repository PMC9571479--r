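---
title: "Discovering circulating microRNA signatures from qPCR array Ct data"
author: "mirsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering circulating microRNA signatures from qPCR array Ct data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

# Background and scope

Circulating microRNAs carried by plasma extracellular vesicles (pEVs) are
candidate diagnostic biomarkers: they are stable in blood, measurable by
RT-qPCR array cards, and their abundance shifts with disease status. A
typical discovery study profiles a few hundred microRNA assays in a small
case/control cohort, derives a sparse multivariate signature, and validates
the fixed signature in independent cohorts.

`mirsig` implements that workflow end to end on cycle-threshold (Ct)
matrices: a Ct is the PCR cycle at which fluorescence crosses the detection
threshold, so *lower* Ct means *higher* abundance and expression is
proportional to $2^{-Ct}$. All stages operate on an S4 container (`CtSet`,
a `SummarizedExperiment` with a `ct` assay) so assay and sample metadata
travel with the values.

The package also ships a seeded synthetic-cohort generator. Raw plasma-EV
Ct matrices from published discovery cohorts are generally not deposited,
so the generator provides cohorts with the statistical structure the
analysis assumes, making every downstream stage testable and every
reported number reproducible from code.

# Preprocessing

**Undetermined reactions.** Reactions that never cross the detection
threshold are exported as the token `Undetermined`. They are parsed into an
explicit censored state and later assigned the maximal cycle number,
Ct = 40 (`imputeUndetermined()`), the standard convention for 40-cycle
array cards. Imputation is idempotent.

**Informativeness.** Ct values above 33 cycles sit in the stochastic
amplification regime and are treated as "not expressed". The default
policy keeps an assay only when Ct $\le$ 33 in *every* sample (matching a
"detected in all samples" analysis set); because published descriptions
rarely state whether detection was required in all samples, per group, or
in a fraction, the policy is a parameter (`filterInformative(policy =
"fraction", q, perGroup)`) rather than a hard-coding.

**Hemolysis QC.** Red blood cells are rich in miR-451 while miR-23a is
stable in plasma, so $\Delta = Ct(\text{miR-23a}) - Ct(\text{miR-451})$
grows in hemolyzed samples. Samples with $\Delta > 7$ cycles fail QC and
are excluded before normalization; $\Delta \in (5, 7]$ raises a warning
flag. These cutoffs follow the established hemolysis-QC literature for
plasma microRNA work. A censored marker leaves the sample `inconclusive`
(kept, flagged).

# Normalization and method selection

Five candidate methods are implemented (`normalize*()`), all on the Ct
scale:

* **quantile** — each sample's $k$-th order statistic becomes the mean of
  all samples' $k$-th order statistics (ties receive the mean of the span);
  afterwards all samples share one value multiset exactly.
* **geometric mean** — geometric-mean scaling on the linear $2^{-Ct}$
  scale equals arithmetic-mean centering on the Ct scale; each sample is
  shifted to the grand mean.
* **delta-Ct** — subtract, per sample, the mean Ct of control assays
  (defaulting to the flagged spike-ins).
* **scale rank-invariant** — anchor on assays whose rank is stable between
  each sample and the pseudo-mean reference (rank shift $\le$ 5% of the
  panel, extreme 5% tails excluded, minimum set size 5), then shift each
  sample by the mean difference over the common anchor set.
* **norm rank-invariant** — per sample, fit a lowess curve mapping sample
  Ct to reference Ct over that sample's rank-invariant set and transform
  all Cts through it (linear extrapolation beyond the set's range). This
  also removes smooth intensity-dependent distortions.

The rank-invariant parameters (5%/5%/floor 5, pseudo-mean reference,
linear extrapolation, lowess span 2/3) are fixed, documented defaults in
the spirit of the qPCR-array analysis tools that popularized these
methods; the methods are named but not specified formula-by-formula in the
literature, so the exact constants are package design decisions. Degenerate
anchor sets trigger an explicit fallback chain (norm $\to$ scale $\to$
global mean) with warnings.

`selectNormalization()` runs every method and scores each by the mean
per-assay standard deviation and coefficient of variation (CV = SD/|mean|)
across samples; the method with minimal mean CV wins, ties broken by mean
SD and then by a fixed method order. CV is computed on the Ct scale, where
means are safely positive for raw Ct; for delta-Ct output the absolute
mean is used so the score stays nonnegative. Whether CV/SD are averaged
per assay (default) or pooled is exposed via `by =`.

# Differential expression

For each assay, $\Delta\Delta Ct = \overline{Ct}_{patients} -
\overline{Ct}_{controls}$ and fold change $= 2^{-\Delta\Delta Ct}$. An
assay is called differentially expressed when fold change $\ge 2$ (up) or
$\le 0.5$ (down) *and* the two-sided Wilcoxon rank-sum p-value is below
0.05. "Fold change > |2|" is read symmetrically ($|\log_2 FC| \ge 1$),
since signatures typically contain both directions. The exact permutation
distribution is used for small tie-free comparisons (combined $n \le 20$),
otherwise the normal approximation with tie and continuity corrections.
No multiple-testing correction enters the default call — the filter is on
raw p, as is customary for qPCR panel screens — but Benjamini–Hochberg
q-values are always reported alongside and can drive the call via
`useQValue = TRUE`. Hierarchical clustering of samples on the DE set uses
1 − Pearson correlation with average linkage by default (the literature
rarely states these choices; both are configurable).

# Signature selection

The candidate matrix is samples × DE assays of normalized Ct values, with
patient = 1 as the positive class. An L1-penalized logistic path is fitted
with `glmnet` (features standardized internally; coefficients reported on
both the raw per-cycle and the per-SD scale). The penalty is chosen by
stratified 10-fold cross-validation of the binomial deviance and the
one-standard-error rule: the largest $\lambda$ whose CV error is within
one SE (across folds) of the minimum. Fold assignment is seeded and
recorded. Held-out fold probabilities are capped at $10^{-5}$ from the
boundary so deviances stay finite under separation.

**Bootstrap stability.** The cohort is resampled with replacement
(default B = 10000, the protocol scale for this analysis family) and the
*entire* selection — path, CV, extraction — is rerun per resample.
A resample "recovers" the signature when it selects at least half of the
original assays. We report the recovery frequency and define the
stability p-value as 1 − frequency, so that small p indicates a stable,
well-supported signature; the raw frequency is always reported alongside
because the opposite convention also appears in the literature.

**Random-signature null.** To ask whether a signature of size $k$ could
perform as well by chance, M random $k$-subsets of the candidate pool
(default: all informative assays; configurable) are fitted as unpenalized
logistic models on the training cohort and scored on the test cohort under
the same threshold protocol as the real signature. The p-value uses the
add-one convention $(1 + \#\{acc_{rand} \ge acc_{obs}\})/(M+1)$, which
cannot return exact zeros.

A calibration caveat worth knowing: accuracy at a cohort-recalibrated,
TPR-maximizing threshold has an atom at the prevalence (the minimum
predicted patient probability undercuts every control with probability
one half under exchangeability), so null p-values computed this way are
discrete and conservative rather than exactly uniform under label
permutation. This is a property of the accuracy-at-recalibrated-threshold
statistic itself, not of the implementation; the package's acceptance
suite demonstrates it.

# Evaluation

**LOOCV.** Classification performance on the discovery cohort uses
leave-one-out cross-validation: the logistic coefficients are refitted on
each $n-1$ subset with the signature fixed (feature selection is *not*
redone inside the loop, matching the protocol this analysis family
reports; a stricter selection-inside-LOOCV can be composed from the
exported pieces). Separated folds fall back to a ridge-stabilized fit
(L2 penalty $10^{-4}$) and are flagged.

**Curves.** ROC points, trapezoidal AUC (equal to the Mann–Whitney
statistic with half credit for ties) and the DeLong 95% CI come from
`pROC`. Precision–recall points are computed at every unique threshold,
the area by trapezoidal integration over recall (anchored at recall 0
with the precision of the most stringent threshold); because no closed
form exists for a PR-AUC CI, a stratified bootstrap (default 2000
replicates, seeded) supplies the 95% interval.

**Threshold.** The decision threshold "minimizes the false positive
rate". Taken literally that rule is degenerate — the all-negative
classifier has FPR 0 — so the default rule first maximizes TPR, then
minimizes FPR among TPR-maximal candidates, then prefers the larger
threshold; on separable data this lands at TPR 1, FPR 0, and it is the
only reading consistent with reported sensitivities of 1.00. The literal
rule is available as `rule = "literal_min_fpr"` for comparison. Ties at
the threshold predict positive (`prob >= threshold`). When a validation
cohort differs in composition from the discovery cohort, the threshold is
re-selected on that cohort (`recalibrateThreshold = TRUE`, the default),
and metrics at the stored discovery threshold are reported alongside.
Zero-denominator rates are reported as explicitly undefined, never as
silent `NaN`.

# The synthetic cohort generator

`simConfig()`/`simulateCohort()` generate
$$Ct_{fs} = \beta_f - e_f\,[s \in \text{patients}] + o_s + \varepsilon_{fs},
\qquad \varepsilon_{fs} \sim N(0, \sigma^2),$$
with per-assay baselines $\beta_f \sim U(20, 33)$, per-sample offsets
$o_s \sim N(0, \sigma_o^2)$ emulating library/loading effects, planted
effects $e_f$ in cycles (positive = up in patients = lower Ct), and
right-censoring: values above 40 cycles are recorded as `Undetermined`.
Spike-in assays (named after the common plant/worm spike-ins) carry no
group effect and no sample offset, so delta-Ct normalization against them
is exactly recoverable. The hemolysis markers miR-23a/miR-451 are always
on the panel; a configurable fraction of samples is simulated as
hemolyzed by lowering Ct(miR-451) until the marker delta exceeds the
failure threshold.

Defaults are fixed once as the emulated study conditions: 754 assays
(the size of a two-card TaqMan human miRNA panel), 16 patients vs 22
controls, four planted assays at |effect| = 3 cycles (miR-412-3p,
miR-507, miR-1203 up in patients; miR-362-3p down), noise SD 0.5 and
offset SD 0.5 cycles. Planted-assay baselines are drawn from $U(22, 27)$
— a biomarker must live in the well-detected range to survive the
informativeness filter, exactly as real discovered signatures do.
`hemolysisFraction` defaults to 0 because the emulated cohort sizes are
post-QC counts. `simulateValidationCohort()` reuses a discovery cohort's
truth (assay universe, baselines, planted effects, optionally overridden
effect sizes) with fresh samples, offsets and noise.

What the generator does *not* emulate: plate/card layout and positional
effects, PCR efficiency differences between assays, melt-curve artifacts,
correlated assay blocks (co-regulated microRNA families), and non-Gaussian
heavy-tailed noise. Passing tests therefore demonstrate the pipeline's
correctness and its behavior under the assumed error model, not
performance guarantees on real plasma-EV data. No distributional
description of the original raw Ct data exists to calibrate against; all
simulation defaults are stand-ins chosen for testability.

# Numerical and reproducibility choices

* Probabilities inside CV deviances are capped at $[10^{-5},
  1-10^{-5}]$; separated logistic fits fall back to ridge ($\lambda =
  10^{-4}$) and are flagged.
* The penalty for extraction snaps to the nearest grid point; signature
  assays are ordered by decreasing absolute standardized coefficient.
* Normalization-method ties break by mean SD, then the fixed order
  quantile, scale rank-invariant, norm rank-invariant, geometric mean,
  delta-Ct.
* One global pipeline seed deterministically derives per-stage seeds by
  stage-name hashing, so any stage can be rerun in isolation; every seed
  is recorded in the run manifest, and identical configs give
  bit-identical results.
* Empty results are contracts, not crashes: an empty informative set or
  an empty signature is returned with a warning and downstream stages are
  skipped and marked in the manifest.

# Problem sizes used by the test suite

The suite exercises the full generator defaults (754 × 38) for the
end-to-end checks, 50 generator seeds for signature-recovery rates, 20
seeds × B = 500 resamples for the pure-noise stability property, and 100
replicates × M = 200 for null-model calibration — sizes chosen so the
whole suite completes in minutes while keeping Monte-Carlo error well
below the margins being asserted. The bootstrap and null-model defaults
in `runPipeline()` itself remain at the protocol scale (B = 10000,
M = 1000).

# Limitations

* The rank-invariant constants are sensible defaults, not fitted to any
  particular platform; panels with widespread differential expression can
  degenerate the anchor set (the fallback chain then engages).
* LOOCV with selection done once on the full cohort is the protocol this
  family of studies reports, but it is optimistically biased relative to
  nested selection; treat discovery-cohort metrics accordingly.
* The random-null p-value is conservative under ties (see above).
* Wilcoxon p-values for the default cohort sizes use the normal
  approximation with corrections; exact enumeration applies only to small
  tie-free groups.
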