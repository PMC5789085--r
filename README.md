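# mhonet

Transcriptomic signatures of **metabolically healthy obesity (MHO)**.

Some obese individuals (BMI ≥ 30 kg/m²) show none of the metabolic
abnormalities that usually accompany obesity — normal blood pressure,
fasting glucose, insulin sensitivity, lipids and inflammation. `mhonet`
implements, as a tested and reusable R package, a whole-blood RNA-seq
analysis that contrasts such MHO subjects with metabolically abnormal
obese (MAO) subjects through three complementary strategies:

1. **Weighted co-expression network analysis.** Gene–gene Pearson
   similarity `s_ij` is raised to a soft-thresholding power β chosen so
   that the network approximates a scale-free topology (the fit index —
   the R² of the log-log regression of `P(k)` on connectivity `k` — must
   reach 0.8). Modules are detected by UPGMA clustering of the
   topological overlap dissimilarity `1 − TOM` (minimum module size 10)
   and merged when their eigengenes correlate above 0.75. A module is
   associated with MHO status only under a **dual significance rule**:
   the sex-adjusted eigengene–trait correlation has BH-FDR q ≤ 0.05,
   *and* module membership (MM = |cor(gene, eigengene)|) correlates
   positively with gene significance (GS = |cor(gene, trait)|) at
   p ≤ 0.05 — the biological-plausibility check that hub genes track the
   phenotype more closely than peripheral genes.
2. **Negative-binomial differential expression.** Per-gene NB GLMs with
   log link and TMM-derived offsets; a common dispersion maximizing the
   summed Cox–Reid adjusted profile likelihood with tagwise shrinkage
   (prior df 10); likelihood-ratio tests of the group coefficient;
   genes with |log2FC| > 0 and FDR ≤ 0.05 are called differentially
   expressed; deviance goodness-of-fit screening; a power simulation
   over fold-change × abundance strata.
3. **Balanced random forests.** Each tree is grown on an equal-class
   (minority-sized) stratified bootstrap with `mtry = p/2`; OOB votes
   give error, AUC, sensitivity and specificity; permutation importance
   follows `VIM_k = mean over trees of (errOOB₂ᵏ − errOOB₁)`; a
   data-driven selection step finds the smallest gene subset that
   preserves the OOB AUC, and nested RF regressions rank which MHO
   component (CRP, TG/HDL, glucose, HOMA-IR) drives module-gene
   expression.

The clinical phenotype itself (`classifyMHO()`) implements the three
published MHO definitions, the pipeline default being the strictest:
no hypertension (BP ≤ 130/85, no medication), glucose ≤ 100 mg/dl,
HOMA-IR ≤ 5.1, TG/HDL ≤ 1.65 (M) / 1.32 (F), and hsCRP ≤ 0.3 mg/dl.

No real cohort data are required: the package ships a **seeded
synthetic cohort generator** (`generateCohort()`):
NB counts with library-size variation, latent-factor co-expression
modules (one shifted down in MHO subjects), and clinical covariates
drawn from the published group-specific distributions (8 MHO vs 21 MAO).
Every stage of the pipeline is exercised against this generator's ground
truth.

## Worked example

```r
library(mhonet)

cfg <- pipelineConfig(
  simulate = cohortConfig(n_genes = 1200, module_sizes = c(50, 50, 50),
                          seed = 2),
  rf = rfConfig(ntree = 600, nPerm = 600, seed = 1),
  seed = 2)
report <- runFullAnalysis(cfg)
report
#> AnalysisReport (seed 2 )
#>   genes: 1200 -> 1200 after filtering
#>   phenotype: 8 MHO / 21 MAO
#>   soft power: 6 (fit 0.859 )
#>   modules: 3 ; significant: 1
#>   DE genes: 43 of 98 tested
#>   RF ME1 : AUC 0.827
```

Reading the output: the scale-free criterion accepted soft power β = 6
(fit index 0.859 ≥ 0.8); three co-expression modules were detected, of
which one — the planted MHO-associated module — passed the dual
significance rule with a negative eigengene–trait correlation (module
under-expressed in MHO); 43 of its 98 genes were differentially
expressed at FDR ≤ 0.05; and a balanced random forest on its genes
separated MHO from MAO with an out-of-bag AUC of 0.83 despite the
8-vs-21 class imbalance.

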