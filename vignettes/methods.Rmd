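---
title: "Methods: co-expression networks, NB differential expression and balanced forests for the MHO phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mhonet` analyses whole-blood RNA-seq count data from obese subjects
classified as metabolically healthy (MHO) or metabolically abnormal
(MAO). This vignette is the package's own account of the models it
fits, the parameters that matter, the numerical choices made where the
design was open, and what the synthetic-cohort tests do and do not
demonstrate.

## The phenotype

`classifyMHO()` implements three nested published definitions. The
pipeline default (Definition 3) requires, in an obese subject
(BMI ≥ 30): no hypertension — SBP ≤ 130 **and** DBP ≤ 85 **and** no
blood-pressure medication —, fasting glucose ≤ 100 mg/dl,
HOMA-IR ≤ 5.1, TG/HDL ≤ 1.65 (male) / 1.32 (female), and
hsCRP ≤ 0.3 mg/dl. All comparisons are inclusive, exactly as the
cut-offs are stated. A missing required field is an error, never a
silent pass: the target cohort had complete covariates, so imputation
would only hide data problems. The hypertension criterion is read as
the conjunction of both pressure bounds plus the medication flag; this
is one of two defensible readings of "BP ≤ 130/85" and the stricter
one.

## Preprocessing

Counts are filtered **before** normalization: a gene is kept when it
reaches `min_cpm = 1` count per million (raw-library CPM) in at least
`min_samples = 3` samples. Filtering on raw rather than TMM-scaled CPM
is a choice; with ~1 % scale factors the difference is confined to
boundary genes. TMM scale factors follow the published weighted
trimmed-mean-of-M-values algorithm with its standard defaults — 30 %
two-sided trim on M-values, 5 % on average abundance, inverse
asymptotic-variance weights, reference column by the upper-quartile
rule — and are rescaled to geometric mean 1. The implementation is
self-contained; the test suite checks it to 1e-10 against the edgeR
implementation as an independent oracle. Exact invariance of the
factors to depth-rescaling a sample does *not* hold (the precision
weights and the reference rule depend weakly on absolute depth); the
property is asserted approximately (|Δ| < 0.03 under 4× rescaling).

Log expression is `log2((count + 0.5) / (effective libsize + 1) × 1e6)`
— the customary half-count prior keeps zeros finite and the transform
monotone.

PCA outlier flagging standardizes the top 2 principal-component scores
and flags samples farther than 3 SDs from the centre. Scores are
median-centred but **SD-scaled, not MAD-scaled**: with a few dozen
samples the principal scores of high-dimensional data are heavy-tailed,
and MAD scaling flagged ~20 % of perfectly homogeneous simulated
cohorts while SD scaling was calibrated; this deliberately trades some
masking resistance for a usable false-positive rate at n ≈ 29.

## Network construction

The similarity is the gene-wise Pearson correlation; zero-variance
genes are an error rather than silently dropped, to keep gene indexing
stable. The unsigned adjacency is `a_ij = |s_ij|^β`. The soft power β
is the **smallest** candidate in 1…20 whose scale-free fit index
reaches `fit_required = 0.8`; the fit index is the R² of the log-log
regression of binned degree frequency on binned mean connectivity
(10 equal-width bins, empty bins dropped), set to 0 when the slope is
non-negative so that an *increasing* degree distribution can never
pass. When no candidate passes, a typed error carries the full fit
curve so a caller can lower the requirement explicitly. Noise-only
data at high powers can legitimately reach the criterion (most
connectivities collapse toward zero, which looks scale-free to the
binned regression); the criterion is a structural requirement, not a
test against randomness.

The topological overlap is the standard unsigned
`TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 − a_ij)`,
with `TOM_ii = 1`; the matrix implementation is verified against a
brute-force double loop to 1e-10. Modules come from UPGMA
(average-linkage) clustering of `1 − TOM` with a **static** cut at
`cut_height = 0.99` and minimum module size 10. A static cut was
chosen over dynamic branch cutting because it is a single reproducible
parameter and recovers planted modules at the study scale; it is a
config knob, and at much smaller gene counts the cut interacts with
the (lower) selected power, so reduced-size runs should not expect the
default to separate background genes. Average linkage is monotone;
floating-point height inversions from `hclust` are repaired by a
running maximum before cutting. Modules whose eigengenes correlate
above `merge_cor = 0.75` are merged iteratively (largest correlation
first, eigengenes recomputed after every merge).

## Module–trait association

The module eigengene is the first principal component of the
gene-standardized module submatrix, scaled to unit variance and signed
to correlate non-negatively with the module's mean standardized
expression. MM is reported as the absolute correlation with the
eigengene (the signed value is kept as an attribute), GS as the
absolute correlation with the trait (point-biserial for the binary
MHO indicator, MAO coded 0).

Sex adjustment is a partial correlation: eigengene and trait are both
residualized on the covariates, the residual correlation is tested
against a t distribution with `n − 2 − #covariates` degrees of freedom,
and BH adjustment runs across modules. The association is flagged only
under the dual rule: q ≤ 0.05 **and** MM–GS correlation > 0 with
p ≤ 0.05 over the module's member genes only. Gene-set enrichment is
the one-sided hypergeometric tail (equivalently Fisher's exact test),
BH-adjusted across sets.

## Differential expression

Each gene is modelled as NB with log link and `log`(effective library
size) offsets. Dispersion estimation is a deliberately simple
two-level scheme rather than a reimplementation of a trended pipeline:
the common dispersion maximizes the summed Cox–Reid adjusted profile
likelihood (APL; IRLS fit at fixed φ, adjustment
`½ log det(XᵀWX)`), and tagwise dispersions maximize
`APL_g(φ) + prior_n · meanAPL(φ)` with `prior_n = prior_df /
residual_df` and `prior_df = 10`, evaluated on a 13-point log-spaced
grid spanning `common × 2^±6` and spline-interpolated. `prior_df = Inf`
collapses every gene to the common value. IRLS runs at most 50
iterations to a relative log-likelihood tolerance of 1e-8 with the
linear predictor clamped to ±45; non-converged or all-zero genes are
reported as NA rather than guessed.

The LRT compares the full model (intercept + group + covariates) to the
model without group; `LR = 2(ℓ_full − ℓ_reduced)` is clipped at zero
and referred to χ²(1). log2FC > 0 means higher in MHO. A gene is
declared DE when |log2FC| > 0 and BH q ≤ 0.05. The deviance
goodness-of-fit screen refers the residual deviance to χ² with the
residual df and flags p ≤ 0.01 — the flagging threshold is this
package's choice for an inspection-oriented screen. In the
pipeline, DE is restricted by default to associated-module genes, so
the multiple-testing universe is that restricted set; `de_all_genes`
overrides.

The power simulation plants equal numbers of DE and null genes per
(|log2FC| × mean-count) cell at a user-stated dispersion and reports
the fraction of truly-DE genes at q ≤ FDR (default 0.15). It
characterizes the test's operating behaviour (null level,
monotonicity in abundance); power figures for any particular cohort
depend on that cohort's empirical dispersions, so no published number
is a target here.

The ΔΔCt helper uses the arithmetic mean of reference-gene Cts
(equivalent to the geometric mean of reference quantities) and a fixed
amplification efficiency of 2.

## Balanced random forests

"Balancing the prediction error" is realized as a stratified bootstrap
drawing the minority-class count from **both** classes, with
replacement, per tree — with 8 MHO vs 21 MAO each tree sees 8 + 8.
`mtry = floor(p/2)` exactly as specified (not the conventional √p).
OOB votes are accumulated only from trees where the sample is out of
bag; AUC is the rank statistic of the vote fractions with tied pairs
counted one half (verified against exhaustive pairwise comparison);
sensitivity/specificity threshold votes at 0.5, a tie predicting the
reference class.

Permutation importance implements the per-tree difference reading
`VIM_k = mean_t(errOOB₂ᵏ_t − errOOB₁_t)`; the formula as usually written places
errOOB₁ outside the summation, which taken literally subtracts a
single tree's error from a sum — the per-tree reading is the standard
and adopted one. The permutation budget `nPerm = 1000` is spread
across trees: `ceiling(nPerm/ntree)` draws, each drawn once across
samples and evaluated within every tree's OOB subset. A constant
feature has VIM 0 by definition. Note that in a forest fit on
informative data, *unused* noise features still show a small positive
importance bias; the "VIM ≈ 0" null property holds for forests whose
labels are independent of all features, and the tests check it there.

Variable selection is an explicit three-step approximation of
heuristic forest-based selection: (1) rank by mean VIM over 25
independently seeded forests; (2) noise threshold = mean + 2 SD of the
magnitudes of negative mean VIMs (negative importances can only be
noise), falling back to the smallest positive mean VIM when none are
negative; features above it form the interpretation set; (3) a nested
forward pass over the ranked interpretation set records each prefix's
mean OOB AUC (5 seeded forests per prefix), and the prediction set is
the smallest prefix within one standard error of the best. With
redundant informative features the prediction set is intentionally
smaller than the informative set — the interpretation set is the
"recovered features" notion. On all-noise input the threshold rule
can still admit a few features by chance; the forward pass then yields
a chance-level AUC, which is the meaningful null behaviour.

Driver ranking fits, per module gene, an RF regression of expression on
the four MHO components and records the top-importance parameter
(native regression permutation importance, unscaled), then classifies
MHO from each parameter alone and from all four, reporting OOB AUCs.
Constant or duplicated parameters are excluded with a warning.

All forest stages are deterministic under a fixed seed; derived seeds
(replicate r uses `seed + r`, forward-pass prefix j uses
`seed + 1000 + 100·j + r`) keep replicates independent yet
reproducible.

## The synthetic cohort

`generateCohort()` draws, for gene g in sample i,

```
counts ~ NB(mu, phi_g),
mu = 2^(baseline_g + loading_g · f_m(i) + group_i · lfc_g) · L_i / L0
```

with per-module standard-normal latent factors `f_m` (the associated
module's factor shifted by −`assoc_effect` in MHO samples, so the
module is *down* in MHO), loadings ~ N(0.8, 0.15) on module genes and 0
elsewhere, baselines uniform on 3–10 log2 counts, dispersions
φ ~ Gamma(shape 2, scale 0.05) (mean 0.1, median ≈ 0.08 — a typical
bulk RNA-seq range, chosen because no empirical dispersions exist for
a synthetic cohort), and log-normal library sizes (meanlog `log(1e6)`,
sdlog 0.2). Defaults are the study conditions: 8 MHO vs 21 MAO,
2,000 genes, three 50-gene modules, `assoc_effect = 1.5`.

Clinical covariates are drawn per group from log-normal distributions
fitted to the published arithmetic mean ± SD (all variables are
positive and right-skewed; the published geometric means support the
shape), sex/smoking/drinking as Bernoulli with the published
proportions, blood pressure from truncated normals consistent with the
published hypertension counts, and TG/HDL coupled to the associated
module's latent factor within groups through a Gaussian copula
(r = 0.6) so the driver-ranking stage has a recoverable ground truth.
Subjects whose draws contradict their assigned group under
Definition 3 are redrawn (`resampleConsistentClinical()`, bounded
retries); the redraw does not retain the subject's factor coupling,
a negligible loss since violators are tail draws.

What the generator does **not** emulate: read-level artefacts,
GC/length biases, batch effects, trended dispersion–abundance
relationships, correlated background (non-module) structure, and any
real biology in the gene identities. Passing tests therefore show the
pipeline recovers the structure it assumes, under that structure —
not that results from any real tissue would replicate.

## Problem sizes used by the tests

The packaged checks run the full study-scale default (2,000 genes,
29 samples) once for the network/recovery/forest checks; null
calibrations use 20 seeds at 600 genes and 2,000-gene single-run DE
nulls; forests use 200–2,000 trees with the permutation budget scaled
to the tree count. These sizes were chosen so the whole suite
exercises every stage at the cohort's sample size while remaining quick
to run; `ntree = 10,000` and `nPerm = 1000` remain the analysis
defaults in `rfConfig()`.

## Known limitations

- The static dendrogram cut is scale-sensitive (see above); dynamic
  branch cutting is not implemented.
- Signed/hybrid networks, block-wise decomposition for very large gene
  sets, trended dispersions and quasi-likelihood F-tests are out of
  scope.
- The hypergeometric enrichment takes flat gene sets (GMT); no
  ontology-graph propagation.
- Real-data headline quantities (module counts, per-gene fold changes,
  real-cohort AUCs) require real cohort data and are not reproduced by
  the synthetic cohort.
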