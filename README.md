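# bonemet

Molecular subtyping of prostate cancer bone metastases from bulk gene
expression profiles.

Bone metastasis is the lethal end-stage of prostate cancer, and metastases
from different patients behave very differently under androgen-deprivation
therapy (ADT). `bonemet` implements, as a reusable R package plus a set of
numbered analysis scripts, the complete workflow for separating bone
metastases into molecular subtypes and tying those subtypes to tissue
markers and patient outcome:

1. **Preprocessing** of bead-array-style expression cohorts: probe filtering
   against 2× the mean background, per-cohort quantile normalization, probe
   collapse to gene level (highest-median probe), inner-join merging across
   cohorts, and per-cohort probe centering, which removes additive per-probe
   batch effects exactly.
2. **Subtype discovery**: PCA (by SVD) with sevenfold element-wise
   cross-validated Q² per component; Ward/Euclidean clustering of the first
   two PC scores cut at k = 3 defines the reference subtypes (A: luminal,
   AR-driven; B: dedifferentiated, high proliferation; C: stroma-enriched);
   four further algorithms (Ward/Manhattan, k-means, SOM, affinity
   propagation) across three input spaces quantify robustness through a
   grouping-preservation statistic based on optimal cluster matching.
3. **Classification**: per-subtype marker panels (top 20 genes by one-vs-rest
   Mann-Whitney U with linear-scale median fold change ≥ 1.5) feed an
   OPLS-DA model — PLS-DA with the class-uncorrelated (orthogonal) variation
   removed first — predicting dummy-coded class values **ŷ**; a sample is
   assigned to a class iff exactly one ŷ > 0.65 and the others are < 0.35,
   is *intermediate* when any ŷ ∈ [0.35, 0.65], and *unassigned* when all
   ŷ < 0.35.
4. **Immunohistochemistry**: the immunoreactivity score IR = distribution
   bin (0–4) × intensity grade (0–3) ∈ 0–12, and the combinatory PSA/Ki67
   grouping (PSA IR dichotomized strictly above the cohort median, Ki67 at
   the cohort upper quartile) that separates good-prognosis
   highPSA/lowKi67 tumors from poor-prognosis lowPSA/highKi67 tumors.
5. **Survival and statistics**: Kaplan-Meier with cause-specific censoring
   (prostate-cancer death as event, time from first ADT), log-rank, Cox
   models with Breslow ties, Kruskal-Wallis/Mann-Whitney/Wilcoxon/Spearman/
   chi-square utilities.
6. **Enrichment**: hypergeometric over-representation of gene sets (GMT) and
   over-connectivity of upstream regulators in a directed network, both
   Benjamini-Hochberg adjusted.

A synthetic-cohort generator (`generate_cohort()`) plants all of this
structure — three subtypes at 71/17/12%, two batches with additive
per-probe offsets, subtype-dependent exponential survival (medians 49/25/43
months), negatively rank-correlated PSA/Ki67 immunoreactivity (Spearman
≈ −0.32) — so every stage is testable without any external data. See the
methods vignette (`vignettes/bonemet-methods.Rmd`) for the model behind each
stage and all defaults.

## Worked example

```r
library(bonemet)

cohort <- generate_cohort(synth_config(seed = 7))   # n = 72, 1000 genes
pp  <- preprocess_cohort(cohort$expression)
sol <- discover_subtypes(pp, m_components = 2, k = 3, seed = 7)
print(sol)
#> ClusterSolution: k=3 on pc2; n=72 samples
#> cluster sizes: 51/12/9
#> preservation:
#>   ward_manhattan.pc2                  1.00
#>   kmeans.pc2                          1.00
#>   som.pc2                             1.00
#>   affinity_propagation.pc2            0.50
#>   ...
adjusted_rand(sol$reference_labels, cohort$truth)
#> [1] 1
```

The reference clustering recovers the planted 51/12/9 subtype split exactly
(adjusted Rand index 1); the k-aware alternative algorithms preserve 100% of
the grouping, while affinity propagation (emergent k = 4 under its default
preference) splits the dominant cluster — the workflow reports rather than
forces its solution.

```r
panel <- select_markers(pp, cohort$truth)           # top-20 per subtype
X     <- t(pp$values[panel_genes(panel), ])
model <- fit_oplsda(X, cohort$truth)
print(model)
#> OplsdaModel: 3 classes (A/B/C), 60 genes, 2 predictive + 0 orthogonal components
#> thresholds: <0.35 out, >0.65 in

validation <- generate_cohort(synth_config(seed = 1007))
val <- external_validation(model, panel, preprocess_cohort(validation$expression))
round(val$frequencies, 3)
#>     A     B     C
#> 0.708 0.167 0.125
```

Applied to an independently generated cohort, the classifier reproduces the
planted subtype frequencies (70.8/16.7/12.5%).

```r
clin <- cohort$clinical
spearman_cor(clin$psa_ir, clin$ki67_pct)$rho
#> [1] -0.270259
comb <- combinatory_score(clin$psa_ir, clin$ki67_pct)
round(attr(comb, "frequencies"), 3)
#>  highPSA_lowKi67   lowPSA_lowKi67  lowPSA_highKi67 highPSA_highKi67
#>            0.458            0.292            0.208            0.042
```

Tissue PSA and Ki67 are inversely correlated and the double-high group is
the rarest, as the combinatory grouping expects.

The same steps, with commentary and saved tables under `results/`, run as a
pipeline:

```sh
Rscript analysis/01_simulate.R     # synthetic discovery + validation cohorts
Rscript analysis/02_preprocess.R   # normalize, collapse, center
Rscript analysis/03_discover.R     # PCA + consensus clustering
Rscript analysis/04_classify.R     # marker panels + OPLS-DA + validation
Rscript analysis/05_ihc_survival.R # IR scores, combinatory groups, KM/Cox
Rscript analysis/06_enrich.R       # set over-representation, regulator network
```

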