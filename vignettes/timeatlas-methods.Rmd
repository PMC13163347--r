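---
title: "Methods: multicellular modules, meta-programs and the regulon risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicellular modules, meta-programs and the regulon risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`timeatlas` re-implements, as reusable and tested functions, a single-cell
analysis workflow for the tumor immune microenvironment (TIME) of
driver-mutated non-small cell lung cancer: how cell subpopulations co-occur
across patients (cellular modules, CMs), what transcriptional states cancer
cells adopt (gene elements, GEs), which ligand–receptor axes connect the
two, and how regulon activity translates into a prognostic risk score. This
vignette documents the statistical model behind each stage, the parameters
that matter, and the choices made where the underlying procedure left the
design open.

## The synthetic cohort and what it does (not) emulate

Every stage can be exercised without external downloads through
`cohort_config()` and the `simulate_*()` generators, which also record the
planted ground truth used by the recovery tests.

**Composition.** Patient-by-subpopulation frequencies follow a
logistic-normal model: subpopulations of module $m$ share a latent Gaussian
factor with loading $\sqrt{\rho}$ ($\rho$ = `within_module_corr`),
independent Gaussian noise supplies the remaining unit variance, an extra
jitter of sd `composition_noise_sd` is added, and each patient's latent
vector is closed to the simplex by softmax. This is the simplest
simplex-valid model with a tunable co-occurrence strength; the reference
conditions are 200 patients, 30 subpopulations, 5 modules, $\rho = 0.8$ and
noise sd 0.1.

**Expression.** Gene baseline means are log-normal, library sizes are
log-normal (`meanlog = log(5000)`, `sdlog = 0.3`), and counts are negative
binomial with dispersion 0.4 (variance $\mu + 0.4\mu^2$), the standard
droplet-data noise model; dispersion 0 gives the Poisson limit. Cells carry
at most one planted program whose genes get their means multiplied by
$e^{\text{effect}}$ (reference: 5 disjoint 60-gene programs at effect
$\ln 4$ among 1,000 genes, 3,000 cells spread over 10 pseudo-samples with
every program present in every sample). The generator does **not** emulate
batch effects, doublets, ambient RNA or spatial structure; passing recovery
tests therefore shows the pipeline's statistical machinery works under its
assumed noise model, not that real datasets with batch structure will
behave identically (batch integration is an upstream concern here).

**Survival.** Event times are exponential with rate
$\lambda_0 e^{\sum_i \beta_i s_i}$ over per-patient regulon scores, censored
by an independent exponential; `baseline_rate` defaults to 0.1 events per
time unit and `censor_rate` to 0.05, giving realistic event fractions
(~70–80%) at cohort scale.

One integer seed governs a whole cohort; each stage derives a stable
sub-seed via `derive_seed()`, so stages are independently reproducible and
any run can be replayed from the manifest.

## Quality control, normalization, clustering, markers

Cells are kept when total UMI lies within `[umi_min, umi_max]`, detected
genes exceed `min_genes` (default 200) and the mitochondrial fraction
(case-sensitive symbol prefix, default `"MT-"`) stays below 25%. The
total-UMI guard is exposed as a min/max pair: the conventional use is an
upper bound around 50,000 as a doublet guard, but both directions are
configurable because QC conventions differ between datasets. Normalization
is `log1p(count / libsize * 1e4)`, which preserves the zero pattern
exactly.

Variable genes are the top 2,000 by dispersion (variance/mean) z-scored
within 20 equal-frequency mean-expression bins; ties resolve by matrix
order so the selection is deterministic, and constant genes can never be
selected. Clustering embeds cells with PCA (30 components by default) on
scaled variable genes, builds a Jaccard-weighted shared-nearest-neighbor
graph (k = 15, weak links below 1/15 pruned) and runs Leiden community
detection under a modularity objective once per resolution; resolutions
spanning 0.01–2 capture both coarse and fine states.

Markers use a one-vs-rest two-sided Wilcoxon rank-sum test per gene with
mid-ranks, tie-corrected variance and continuity correction (numerically
identical to `wilcox.test(correct = TRUE)`, verified to machine precision
against it), `log2FC` computed on `expm1` means with a $10^{-9}$
pseudocount, and BH adjustment within each cluster's family.

## Composition statistics

`roe()` computes the observed/expected ratio
$O_{ij} / (r_i c_j / N)$ on any two-way table of cell counts with the
table-wide Pearson chi-square; entries with a zero margin are reported as
missing rather than zero. `cooccurrence_modules()` correlates subpopulation
frequencies across patients (Pearson; p from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, both raw and BH-adjusted) and clusters the
distance $1 - r$ with Ward (`ward.D2`) linkage. $1 - r$ rather than
$1 - |r|$ is deliberate: anti-correlated subpopulations must not share a
module. The number of modules is user-supplied (the workflow this package
systematizes reported five without a stated cut rule); `k = "auto"`
maximizes the mean silhouette width over $k \in 2..10$ when no external
choice exists. `dominant_module()` renormalizes module-summed frequencies
per patient and takes the argmax, ties to the lexicographically smallest
module id so repeated runs agree.

## Meta-program (gene element) discovery

Marker sets from every (sample, resolution, cluster) are filtered
(mitochondrial prefix, adjusted p ≥ 0.05, non-positive log fold change,
expressed in ≤ 20% of the cluster) and truncated to the top 200 by
(padj ascending, log2FC descending). Sets under 20 genes are removed, and
near-duplicates (Jaccard > 0.95) are greedily dropped in input order —
sample then resolution ascending — which keeps the earliest occurrence and
makes de-duplication deterministic; permuting input order can swap which of
two near-duplicates survives but not the program structure recovered from
planted data.

Consensus clustering treats the rows of the Jaccard matrix as feature
vectors (each set described by its similarity profile), optionally
L2-normalized so k-means behaves spherically. For each candidate $k$, 50
resamples of 80% of the rows are clustered and the consensus matrix records
co-clustering frequencies among resamples containing both sets. $k$ is
chosen by the minimum proportion of ambiguous clustering (PAC: the fraction
of consensus entries in (0.1, 0.9)), ties to the smaller $k$. Two
degenerate conventions are declared: a flat PAC profile (range < 0.01) or a
minimum PAC above 0.5 — both symptoms of structureless input where no
partition is unambiguous — fall back to the smallest candidate $k$. The
final partition cuts an average-linkage tree on $1 - \text{consensus}$.
Program signatures rank genes by recurrence across member sets (retained at
recurrence ≥ 0.25, capped at 50 by default; the signature-construction rule
is this package's own, as the upstream procedure never states one).

## Scoring engines

* `module_score()`: mean expression of the signature minus the mean of
  `n_ctrl` (default 100) control genes drawn per signature gene from its
  average-expression bin (25 equal-frequency bins), without replacement
  where the bin allows, gene itself excluded, seeded. Expected value 0 for
  a bin-matched random signature.
* `auc_score()`: recovery-curve AUC of signature genes within the top 5%
  of each unit's expression ranking, normalized to the maximum attainable
  area; ties are broken by a seeded random order so results are reproducible.
  Invariant under monotone transformations of expression.
* `ssgsea_score()`: single-sample rank-weighted enrichment — the summed
  difference between the in-set ECDF weighted by $|\text{rank}|^{0.25}$ and
  the uniform out-of-set ECDF. This is a documented substitution for
  kernel-ECDF GSVA scoring: downstream stages need any monotone per-sample
  set score, not that package's exact kernel.
* `ulm_activity()`: per TF and unit, the t-value of the slope from
  regressing the unit's expression profile on the TF's target-weight vector
  over the whole gene universe (non-targets weigh 0); regulons with fewer
  than 5 present targets are dropped. Verified against `lm()` to $10^{-8}$.
* Regulons of 2–3 genes (TF plus ligand/receptor) are scored by mean
  expression instead of rank enrichment (`score_regulons()`): a rank
  statistic over two genes is dominated by discreteness noise.
* `hypergeom_enrich()`: upper-tail hypergeometric p with BH q-values,
  retention at p < 0.05 and q < 0.2.

## Communication scoring

`lr_communication()` is a declared simplification of full communication
probability models: cluster-level ligand and receptor expression are mean
log-normalized values, multi-subunit complexes take the minimum over
subunits (limiting-subunit semantics; absent subunits count as zero), the
score of sender → receiver for a pair is the product, and significance
comes from global permutation of cluster labels with the standard
$(1 + \#\{ \text{perm} \ge \text{obs}\})/(n_{perm}+1)$ estimator, which
floors p at $1/(n_{perm}+1)$ and never returns zero. Cofactors, Hill-type
saturation and pathway aggregation beyond a plain sum over member pairs are
intentionally out of scope. Clusters under 50 cells are excluded before
scoring. Calibration is verified empirically: under a permuted-label null
the rejection rate at 0.05 stays within Monte-Carlo error of nominal.

## Survival analytics and the risk model

Kaplan–Meier estimation, log-rank tests and Cox partial-likelihood fits
(Efron tie handling) delegate to the survival package; the test suite
checks them against hand-rolled risk-set-enumeration oracles to $10^{-10}$
on small fixtures. `optimal_cutpoint()` evaluates every midpoint of
consecutive sorted unique scores that leaves both groups with at least
`minprop` (default 0.1) of the patients, scores each by the standardized
two-group log-rank statistic and returns the maximizing cutoff (optional
seeded permutation p re-maximizes over permuted scores, accounting for the
selection).

The risk model is the two-stage screen-then-shrink procedure: univariate
Cox per candidate regulon keeps p < 0.05; an L1-penalized Cox fit over the
survivors picks $\lambda$ at the 10-fold cross-validated partial-deviance
minimum (the minimum rather than the 1-SE rule — the sparser 1-SE choice is
a defensible alternative, but the deviance minimum is the neutral default
when the upstream procedure states only "10-fold cross-validation"; the
choice is recorded in the fitted object and the fold assignment is seeded).
A single stage-1 survivor is fit unpenalized, which also makes the
$\lambda = 0$ consistency property testable; an empty stage-1 set returns
an explicit `"empty"` status rather than an error. The risk score is the
plain dot product $RS = \sum_i \hat\beta_i s_i$ with no intercept, and
patients split at the median RS (ties to low risk, deterministically).

`time_roc()` implements cumulative-case/dynamic-control AUC with inverse
probability of censoring weights from the Kaplan–Meier estimator of the
censoring distribution (left limits $G(T^-)$); with no censoring it reduces
exactly to concordant-pair counting, which is how it is tested. Horizons
are a required user parameter in the time unit of the records — no default
is asserted, because published workflows mix 1/2/3- and 1/3/5-year
conventions.

`ridge_sensitivity()` imputes drug response per drug by closed-form ridge
regression on training-standardized features,
$\hat\beta = (X^\top X + \lambda I)^{-1} X^\top y$, with $\lambda$ from
10-fold cross-validated MSE over a log grid when `"cv"`; the closed form
makes the OLS ($\lambda \to 0$) and grand-mean ($\lambda \to \infty$)
limits exact.

## Problem sizes and numerical conventions

The reference problem sizes used throughout the tests and the acceptance
script are the generator defaults above (200 patients / 30 subpopulations /
5 modules; 3,000 cells / 10 samples / 5 × 60-gene programs; survival
recovery at n = 600 with 23 candidate regulons, cutpoint recovery at
n = 500). Degenerate inputs have declared behaviors rather than silent
defaults: zero-variance scores and all-`unknown` patients error or drop
with a message, zero-margin Ro/e entries are missing, all-tied risk scores
stratify to low, and Cox non-convergence is reported, never defaulted.
Gene symbols are case-sensitive and never auto-mapped; identifier
harmonization is an input-preparation concern.

## Known limitations

The consensus-clustering internals (similarity-profile features + resampled
k-means + PAC) match the published contract — a stable consensus partition
with automatic k — but are not a line-for-line reproduction of any specific
consensus package; likewise the communication score omits cofactor
modulation, and the single-sample enrichment is ssGSEA-style rather than a
GSVA kernel reproduction. All three substitutions are deliberate, surfaced
in the function documentation, and covered by oracle or calibration tests
at the contract level.
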