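---
title: "Methods: multi-stage proteomic biomarker panel discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stage proteomic biomarker panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

proteoPanel implements a complete analysis chain for aptamer-based
case–control proteomics: matrices of relative fluorescence units (RFU) for
hundreds to thousands of protein assays, measured in serum, cerebrospinal
fluid (CSF) and post-mortem brain tissue, with per-sample clinical
covariates (disease status, age, sex, cohort, MoCA, MDS-UPDRS III, LEDD,
batch). This vignette records the statistical model behind each stage, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## Data model

The central container is `ProteinExperiment`, a `SummarizedExperiment`
subclass with one assay (proteins × samples) and a `transformState` flag
tracking the normalization chain: `raw` (strictly positive RFU), `log2`,
`standardized` (per-protein Z on the log2 scale, sample SD with the n−1
denominator), and `residualized` (covariate-adjusted residuals). Every
stage declares which states it accepts, so an un-normalized matrix cannot
silently enter a scan. Readers accept both common TSV dialects
(samples-in-rows and proteins-in-rows) and validate identifiers, RFU
positivity, MoCA ∈ [0, 30] and UPDRS III ≥ 0 at the boundary.

## Quality control and normalization

* `qcFilterSamples` removes samples whose assay-control scale factor falls
  outside the closed interval [0.4, 2.5]. The interval is treated as
  closed because the bounds are printed without strictness and inclusive
  acceptance is the convention for vendor QC ranges. The factor is
  per-sample; a per-dilution-bin variant would need vendor internals that
  are upstream of this package's inputs.
* `log2AndStandardize` applies log2 then per-protein Z-scoring; a
  zero-variance protein is an error by default (`onZeroVariance = "drop"`
  removes it with a report).
* `residualizeCovariates` replaces each protein by the residuals of an
  ordinary least-squares fit (a Gaussian-link GLM) on named covariates.
  Dates are encoded as days since the dataset's earliest date and treated
  as continuous; character covariates are dummy-coded with the
  alphabetically first level as reference. Samples with missing covariates
  are dropped, with the count reported. Log2 is applied before
  residualization throughout.
* `combatAdjust` performs parametric empirical-Bayes location/scale batch
  adjustment (ComBat, via the sva package) with biological covariates
  protected through the model matrix. A single batch is a no-op; a batch
  with one sample, or a batch perfectly confounded with a protected
  covariate, is an error. Because the per-protein batch effects are shrunk
  toward a common prior, the adjustment equalizes batch means in
  expectation while leaving per-protein residuals at sampling-noise scale —
  the package's tests therefore assert the closed-form behaviour on batch
  averages, and absence of batch structure via the PC scan below.
* `pcConfounderScan` computes top-k principal components by SVD of the
  centered matrix and tests each against each recorded technical variable
  (one-way ANOVA F for categorical, Pearson correlation test for numeric),
  flagging pairs below α (default 0.01).

## Discovery: annealing ranking and nested random-forest panels

`saRankProteins` searches subsets of proteins (size 5–100 by default) by
iterated random perturbation — add, remove or swap one protein, with
probabilities 0.25/0.25/0.5. Subset fitness is the pooled stratified
5-fold cross-validated AUC of an unpenalized logistic model
(`subsetFitness`), matching the downstream evaluation criterion. The
default is 1000 iterations.

Acceptance is greedy with two refinements that required a deliberate
choice:

* **Fitness tolerance.** Cross-validated AUC differences below
  `fitnessTolerance` (default 0.01) are treated as ties: fold-to-fold
  noise in a CV AUC estimate is well above that scale, so smaller
  differences are not evidence of improvement.
* **Parsimony-guarded tie acceptance.** A tie is accepted only if the
  candidate subset is no larger than the current one. Strict
  better-only acceptance freezes permanently on the first subset that
  reaches a fitness plateau, so the final ranking is dominated by
  whichever uninformative proteins happened to be present at that moment.
  Tie acceptance with the size guard keeps the search moving across the
  plateau: informative members persist (removing them costs more than the
  tolerance), uninformative members churn away, and selection counts
  concentrate on the true signal. `acceptTies = FALSE` restores the literal
  strict rule, and a `temperature` option enables classical stochastic
  acceptance of worse candidates; both default off the annealing-schedule
  path because greedy-with-ties is fully reproducible and testable.

Selection counts credit, at every iteration, the members of the reigning
accepted subset, so a subset that survives many iterations accumulates
weight ("how often a protein is selected"); `countMode = "visited"`
credits the proposed candidate instead. Ranks are dense by descending
count, with ties broken lexicographically by protein id so that the top-N
panel is deterministic.

`buildPanelClassifier` trains a random forest on exactly the top-N
proteins (500 trees, ⌊√N⌋ features per split, class-balanced bootstrap —
all exposed), recording out-of-bag accuracy; `sweepPanelSizes` builds one
classifier per N (the published sweep used N = 1…200), each with seed
`seed + N` so any single panel can be rebuilt independently.
`evaluateOnModality` scores a test cohort; panel proteins missing from the
test matrix follow a policy: `drop-refit` (default — refit the forest on
the shared members using the stored training data, mirroring replication
panels reduced by cohort-level QC), `impute-mean`, or `error`.

ROC evaluation uses the Mann–Whitney identity (ties count ½), a
permutation p with the add-one estimator (r+1)/(B+1) over B label
permutations (default 10 000, giving the attainable floor of 1 × 10⁻⁴),
and a stratified percentile bootstrap 95% CI (cases and controls resampled
separately; the interval is clamped to bracket the point estimate, and a
single bootstrap draw yields a degenerate equal-bound interval).

## Signatures and replication

A panel is compressed to one score per sample in two ways: `meanzScore`
(per-protein Z on the log2 scale, then the per-sample mean) and
`eigengeneScore` (first left singular vector of the standardized
samples × panel submatrix, scaled to unit sample variance). The SVD sign
is arbitrary, so the eigengene is anchored to correlate positively with
the mean-Z score and the orientation is recorded. Both scores are
invariant to affine rescaling of any input protein.
`signatureAssociation` regresses the outcome on the score — logistic for
disease status, linear for continuous outcomes — unadjusted by default
(covariates optional); complete logistic separation, detected by warning
flags or an exploded slope/SE, is a flagged error rather than a numeric
result.

## Differential regulation and enrichment

`proteinGlmScan` fits one GLM per protein — binomial link with status as
outcome and protein + covariates (default age, sex, cohort) as predictors;
Gaussian link for MoCA, UPDRS III, or the composite severity score — with
Wald p-values and Benjamini–Hochberg adjustment across converged fits
only. Non-convergent or boundary fits are flagged and excluded from the
adjustment denominator, preserving the FDR interpretation on tested
hypotheses; the same covariate set is used for all outcomes. Samples
missing an outcome are dropped per scan, and motor/cognitive scans use all
samples by default (controls carry low UPDRS III). `targetedPanelScan` is
the unadjusted univariate mode for curated candidate panels — each
candidate is an independent hypothesis, so no multiplicity correction is
applied — with a +/−/· significance matrix at α = 0.05.

`ora` is an exact hypergeometric upper-tail test of a query list against
GMT gene sets: p = P(X ≥ k) with universe size M, in-universe set size K
and query size n, BH-adjusted across tested sets. The universe should be
the assays that passed QC on the relevant panel, not a whole proteome —
an assay-restricted universe avoids inflated enrichment. Defaults:
minimum tested set size 3, minimum overlap 1 (0 includes k = 0 sets at
p = 1 exactly).

## Co-expression modules

`adjacencyTom` builds the unsigned weighted network a_ij = |cor|^β
(default soft power β = 2, per the adapted proteomic pipeline) and the
topological overlap TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 −
a_ij). `detectModules` clusters 1 − TOM by average-linkage hierarchical
clustering with a **static** cut (height 0.85 on the dissimilarity); the
dynamic hybrid cut used by some pipelines is deliberately not implemented
because a fixed cut is fully specifiable and testable. Clusters below the
minimum size (default 30) are grey; matrices above `blockSize` are
pre-partitioned by k-means on the dissimilarity rows (the block-wise
step); modules whose eigengenes correlate above 0.8 are merged. Labels are
colors by descending size. `moduleEigengenes` computes per-module first
principal components (unit variance, sign anchored to positive mean member
correlation), kME for every protein, and the hub as the member with
maximal |kME| (ties lexicographic). `moduleTraitAssociation` regresses
each eigengene on status (logistic) and continuous traits (linear),
including the composite severity score.

## Severity

The composite severity score is the equal-weight mean of z(UPDRS III) and
z(30 − MoCA) over scorable cases — both components increase with severity,
and z-scoring makes the composite invariant to affine rescaling of either
clinical instrument. This construction is a documented substitute: the
original study defines its score only in supplementary material, so the
package adopts the simplest defensible composite and exposes the weights.
`stratifySeverity` labels the bottom 15% mild and top 10% severe by
default (quantile scheme), or splits at the median (odd counts put the
middle case below); ordering ties break by sample id so strata are exactly
reproducible. `stratifiedEvaluation` scores a family of panel classifiers
on {stratum cases} ∪ {all controls} and reports each stratum's best panel
with N, AUC, CI and permutation p.

## The synthetic study generator

`synthConfig`/`generateCohort` emulate the three-cohort, three-modality
study that motivated the pipeline. Signal is planted additively on the
log2 scale and exponentiated to RFU, so planted effects read directly as
log2 fold-changes:

x = baseline + status·effect·attenuation + severity·slope
  + block factors + batch shift + N(0, noiseSd²),   RFU = 2^x.

Defaults follow the published cohort table: serum training 572 samples at
69.9% cases, CSF 85 at 82.4%, brain 37 at 64.9%, serum replication 932 at
81.9% (case counts fixed, not sampled); age means/SDs/ranges and male
fractions per cohort; MoCA and UPDRS III generated as deterministic
monotone transforms of a latent per-case N(0,1) severity plus noise (MoCA
decreasing, UPDRS III increasing, absent for brain donors); LEDD drawn for
cases and exactly 0 for disease-free controls, so it can serve as a
residualization covariate. Two panel generations (defaults 1129 and 4006
assays) share a configurable overlap (default 1047). Correlated blocks
plant within-block correlation ρ through a latent factor with loading
noiseSd·√(ρ/(1−ρ)); `effectSeverityCoupling` scales each case's planted
effects by max(0, 1 + coupling·severity), giving severity-dependent signal
when positive. Because no effect-size distribution is published for the
real signal, the default plants 30 informative proteins at log2 effect 0.6
with noiseSd 0.5 — a moderate signal a serum biomarker study of this size
could plausibly detect.

What the generator does **not** model: aptamer cross-reactivity,
dilution-bin chemistry, heavy-tailed RFU noise, missing assays within a
panel version, and correlation between clinical covariates and proteins
beyond the planted structure. Tests passing on this generator therefore
show internal statistical correctness (calibration, recovery of known
truth, invariances), not real-data performance.

## Numerical choices and degenerate inputs

Standardization uses the n−1 sample SD. Underflowing Wald p-values are
clamped to 1e-300 to stay inside (0, 1]. The TOM is symmetrized against
floating-point asymmetry and its diagonal set to 1. Rank-deficient GLM
designs fall back to NA-coefficient handling (dropped from the Wald
covariance); logistic boundary fits are flagged by |β| > 15 or SE > 50.
Empty strata are skipped with a note; rank ties anywhere break by
identifier so every pipeline stage is deterministic under its seed (R's
default Mersenne-Twister generator; all seeds are function arguments).

## Problem sizes in the bundled reproduction script

`scripts/acceptance.R` regenerates the study at panel sizes of 300/350
assays with a 260-assay overlap and the cohort sizes above — dimensions
chosen so the whole discovery-to-replication chain, including the
1000-iteration annealing run and the panel sweep, completes in a few
minutes while keeping every cohort at its published sample size. The
script prints, among others, cross-modality test AUCs with permutation
p-values, severity-stratified AUCs, planted-protein recovery at BH 0.05,
and the co-expression module recovery index, all recomputed from scratch
under the seed passed on the command line.

## Known limitations

The annealing search optimizes cross-validated AUC within the training
set, so its in-sample permutation p-values are anticonservative by
selection; always evaluate significance on held-out data (the package's
own null-safety test does exactly this). The static tree cut can split
one strong module across branches at unusual correlation levels — the
merge step mitigates but does not eliminate this. ComBat assumes
location/scale batch effects; batch-by-protein interactions beyond that
model are out of scope. The severity composite is a substitute for an
unpublished formula and should be re-derived when the original definition
is available.
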