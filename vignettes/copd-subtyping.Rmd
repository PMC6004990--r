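---
title: "Molecular subtyping of COPD expression cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular subtyping of COPD expression cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdsubtype)
```

## The problem

Chronic obstructive pulmonary disease (COPD) is clinically heterogeneous:
patients with similar spirometry can differ widely in progression and
treatment response. One route to stratification is molecular: cluster
patients by the expression of a curated list of disease-associated
*candidate genes*, treat the clusters as molecular subtypes, and then ask
(i) which candidate genes and pathways drive each subtype, (ii) whether the
subtypes differ in clinical lung function, and (iii) whether a classifier
trained on one cohort recovers the same structure in an independent cohort.

`copdsubtype` implements that workflow end to end on gene-by-sample
expression tables. It assumes summarized, background-corrected input (e.g.
RMA output exported as TSV); raw array processing is out of scope.

## Pipeline model, stage by stage

### Preprocessing

Probe-level rows are collapsed to gene symbols by the arithmetic mean of
all probes annotated to a gene (probes mapping to several symbols
contribute to each). Every gene row is then z-normalized to mean 0 and
sample standard deviation 1 (n−1 denominator); zero-variance rows cannot be
scaled and are dropped into a reported list. The fixed order is collapse →
z-score → subset-to-candidates. Normalizing after collapsing means the
z-scale refers to the gene-level signal actually clustered; the alternative
order differs only through probe-level variance weighting and is not
offered, to keep results unambiguous.

All downstream stages operate on the candidate-gene submatrix; symbols are
matched case-sensitively, since silent case-folding tends to hide
annotation errors rather than fix them.

### Subtype discovery

Samples are clustered by average-linkage (UPGMA) agglomeration on a
sample-by-sample dissimilarity. The default metric is correlation distance,
`d = 1 − Pearson r` (range [0, 2]), the community default for expression
profiles because it ignores per-sample scale; Euclidean distance is
available (`metric = "euclidean"`). Tree fidelity is assessed by the
cophenetic correlation coefficient — the Pearson correlation between the
original dissimilarities and the tree-implied (cophenetic) distances; 1
means the input was exactly ultrametric.

The tree is cut into `k` subtypes (default `k = 3`; the package makes no
claim of automatic model selection, and no silhouette/gap machinery is
used for decisions). Cluster labels are renumbered 1..k by decreasing
cluster size, ties broken by the lexicographically smallest member sample
id, so label numbering — and hence every downstream table — is reproducible
across runs and platforms.

One geometric caveat worth knowing: a class whose expression is pure noise
around the cohort baseline (e.g. healthy controls among cases) is compact
in Euclidean space but has near-zero *mutual correlation*, so under
correlation distance it will not form its own cluster. When the analysis
needs controls to separate at a `k+1` cut, use the Euclidean metric.

### Gene allocation

For every candidate gene and every subtype, the package runs a two-sided
Welch (unequal-variance) two-sample t-test of the subtype's samples against
all remaining samples. Welch is the robust default given unbalanced
subtype sizes. A gene joins a subtype's set when `p < alpha` (default
`alpha = 0.05`, raw p — mirroring the conventional candidate-gene
workflow; Benjamini–Hochberg adjustment is available via `adjust = "BH"`
but off by default). A gene may be significant against the rest in several
subtypes — with z-scored data an elevation in one subtype necessarily
depresses the others, so the per-subtype sets overlap heavily by
construction. The subtype where a gene's |t| is largest is additionally
flagged **primary**, giving a disjoint partition of the allocated genes
alongside the overlapping sets. The cross-subtype intersection of the
allocated sets is reported as the *common genes*.

Genes constant in both groups get `t = 0, p = 1` with a warning rather
than an error, so one degenerate row cannot abort a cohort-scale run.

### Pathway enrichment and deviation scores

Each subtype's allocated gene set is tested for over-representation in
every pathway of a GMT annotation by the one-sided Fisher's exact
(hypergeometric-tail) test, with BH adjustment across pathways within a
query and an `enriched` flag at adjusted `p < 0.05`. The background
universe defaults to the genes present in both the expression matrix and
the pathway annotation; it is an explicit argument because enrichment
results are notoriously sensitive to the background choice. Pathways
enriched in every subtype are the *common pathways*; pathways enriched in
exactly one subtype are that subtype's *unique pathways*.

Each scored pathway P then receives a per-subtype **deviation score**

$$A(P) = \frac{1}{N}\sum_{i=1}^{N}\left(\bar{X}_i - \bar{Y}_i\right)^2,$$

where the sum runs over the `N` genes of P that belong to the subtype's
allocated set, \(\bar{X}_i\) is gene *i*'s mean within the subtype's
samples and \(\bar{Y}_i\) its mean over all samples. `A(P)` is zero iff
the subtype means coincide with the cohort means on every gene, and grows
with how far the subtype's pathway expression deviates from the cohort.
On z-scored input \(\bar{Y}_i = 0\), so `A(P)` reduces to the mean squared
subtype mean — the test suite verifies this identity as a cross-check.
Pathway/subtype pairs with `N = 0` are skipped with a logged reason, never
silently zeroed.

### Clinical association

FEV1, FEV1/FVC and age are compared across subtypes by one-way
fixed-effects ANOVA; sex by the chi-square test of independence on the
subtype-by-sex table without continuity correction. Sex is categorical, so
chi-square is the default even though ANOVA on a 0/1 coding is offered
(`method = "anova"`) for strict replication of workflows that ran
everything through ANOVA. Missing values are dropped per-variable with
logged counts. Units are taken as supplied (the package never rescales
FEV1), and with `k = 2` the ANOVA F reproduces the squared pooled t — a
property the tests assert.

### Per-sample features and SVM subtype predictors

The deviation score is a subtype-level summary; a classifier needs a
per-sample feature. The package uses the sample-level analog

$$d_s(P) = \frac{1}{N}\sum_{i=1}^{N}\left(x_{is} - \bar{Y}_i\right)^2,$$

with the *discovery-cohort* means \(\bar{Y}_i\) as the fixed reference so
the identical featurization applies to new cohorts. Note the Jensen gap:
averaging \(d_s(P)\) over a subtype's samples does **not** equal `A(P)`
(the squared deviation of a mean is at most the mean squared deviation),
which is why both quantities exist separately.

One feature column is built per scored (pathway, subtype) pair, using the
pathway's intersection with that subtype's **primary** genes. This is the
one genuinely open design point in the workflow and the choice matters:
because the overlapping allocated sets are nearly identical across
subtypes, building the per-subtype columns from them makes the three
columns of a pathway collinear and the features nearly class-blind, while
the primary sets (each gene counted only where its differential signal is
strongest) keep each column specific to one subtype. The feature schema —
gene lists plus reference means — is stored inside the model and
serialized with it.

Per subtype, a one-vs-rest soft-margin linear SVM (penalty `C = 1`) is
fitted; the fitted machines are reduced to explicit weight vectors and
biases, so decision scores are plain linear functions and the model
round-trips through versioned JSON. Prediction takes the argmax of the
per-subtype decision scores, ties resolved toward the lower-numbered
subtype (deterministically, and documented rather than silent). Evaluation
uses stratified 5-fold cross-validation with out-of-fold decision scores
pooled per subtype into one ROC/AUC; the fold assignment is a pure
function of the seed. The suite verifies that the pooled-ROC AUC equals
the Mann–Whitney rank statistic on the same scores.

### Cross-cohort validation

An independent cohort is first restricted to the genes shared with the
discovery data and re-z-normalized within itself (the only cross-platform
harmonization performed; no batch correction is attempted). The validation
cohort is clustered on its own, the trained model predicts every
validation sample, and the two labelings meet in a confusion matrix
(predicted classes in rows, cluster classes in columns). Cluster numbering
is arbitrary, so columns are first matched to model classes by the
permutation maximizing the diagonal — found by exhaustive search, which is
exact for the small class counts involved (≤ 8) — and the applied mapping
is recorded. Per column, the *consistency ratio* is the diagonal count
over the column total, reported as a percentage at one decimal.

Significance of each class's ratio is assessed by permuting the predicted
labels across samples (preserving both marginals) `n_permutations` times
(default 10000) and reporting `p = (1 + #{permuted ≥ observed}) /
(n_permutations + 1)`, which is never below `1/(n_permutations+1)` and is
super-uniform under independence. "Randomly sampling samples" is ambiguous
between permutation and resampling, so a resample-with-replacement mode is
provided (`scheme = "resample"`), but the marginal-preserving permutation
is the default null.

## The synthetic-cohort generator

Every stage is testable without downloads through `synth_config()` /
`generate_cohort()`. The generator plants `k_subtypes` subtypes expressed
through a fraction `frac_informative` of the candidate genes: each
informative gene gets a mean shift of `effect_size × noise_sd` in one
randomly chosen subtype, on i.i.d. Gaussian noise per gene — deliberately
matching the z-normalized working scale the pipeline assumes. Pathways are
drawn from the gene universe with a configurable fraction planted to be
enriched for informative genes. Clinical covariates mirror the shape of a
COPD cohort: FEV1 and FEV1/FVC Gaussian per subtype separated by
`clinical_shift` (subtype 2 is generated as the most impaired and most
female, encoding a severity gradient), age Gaussian and shared across
subtypes, sex Bernoulli with subtype-specific proportions. A validation
cohort reuses the discovery mean model, optionally adds a control class
with its own mean vector (default: the shared baseline) and can keep only
a subset of genes to emulate a platform difference.

Default dimensions mirror a blood-expression discovery cohort: 2000 genes,
213 candidates, 229 samples in three subtypes of 98/53/78, with a
560-sample validation draw. No published effect sizes exist for such
cohorts, so `effect_size = 3`, `frac_informative = 0.75`, `noise_sd = 1`
and `clinical_shift = 6` (percent-scale units) were fixed once as a
moderately separated regime — strong enough that the pipeline should
succeed, not so strong that every stage is trivial. One integer seed
drives a root generator from which per-stage substreams are derived, so
adding pathways never perturbs the expression draws and identical configs
are bit-reproducible.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: probe-level noise, batch and site effects,
correlated gene modules beyond the planted block structure, missingness,
and any nonlinear relation between expression and clinical severity.
Passing the suite shows the machinery is correct and calibrated, not that
three subtypes exist in any particular cohort.

## Numerical and testing choices

* **Oracles.** UPGMA heights and cophenetic coefficients are checked to
  1e-10 against a naive O(n³) reimplementation; deviation scores and
  per-sample features to 1e-12 against explicit double loops; Fisher
  p-values to 1e-12 against binomial-coefficient enumeration over all
  margins ≤ 12; Welch t, ANOVA F and chi-square against textbook-formula
  implementations; CV AUC against the rank-sum form.
* **Calibration simulations.** The null allocation rate (planted effect
  zero) must sit within 3 binomial SDs of α. The enrichment-null
  uniformity check uses pathways with expected overlaps of ≥ ~150 genes:
  hypergeometric p-values are discrete and only *super*-uniform, and at
  small expected overlaps their staircase CDF fails a KS comparison
  against U(0,1) for any correct implementation, so the check is sized
  where the continuous limit applies. Chance-level CV AUC is checked on
  480 samples × 10 noise features, where its Monte-Carlo sd (~0.03) is
  small against the ±0.15 acceptance band — pooled CV scores carry
  fold-to-fold shifts that inflate the spread beyond the i.i.d.
  Mann–Whitney formula, so small-n versions of this check false-fail.
* **Degenerate inputs.** Constant genes: dropped at normalization (scale
  undefined) but tolerated inside t-tests (`p = 1` with warning).
  Zero-variance sample columns are an error under correlation distance,
  naming the sample. Empty pathway/subtype intersections are skipped with
  reasons. All-zero feature rows predict deterministically from the
  biases.
* **Reproducibility.** Every stochastic step (generator, folds,
  permutations) is seed-driven; rerunning the pipeline with the same
  config yields byte-identical TSVs, which the suite asserts via
  checksums. Problem sizes in the tests (cohorts of 60–480 samples,
  universes up to 4000 genes, 100–10000 permutations) were chosen to make
  the statistical assertions sharp at interactive runtimes.

## A minimal run

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
coh <- generate_cohort(cfg)
dir <- tempdir()
paths <- write_cohort(coh, dir)
write_gmt(generate_pathway_annotation(cfg, rownames(coh$expression),
                                      coh$truth$informative_genes),
          file.path(dir, "pathways.gmt"))

config <- pipeline_config(
  expression = paths[["expression"]], candidates = paths[["candidates"]],
  gmt = file.path(dir, "pathways.gmt"), clinical = paths[["clinical"]],
  output_dir = file.path(dir, "out"), k = 3, seed = 1)
manifest <- run_pipeline(config)
```

Artifacts land under `output_dir`: `subtypes.tsv`, `allocation.tsv`,
`enrichment_subtype*.tsv`, `deviation_scores.tsv`,
`clinical_association.tsv`, `cv_metrics.tsv`, `roc_subtype*.tsv`,
`svm_model.json`, optional validation tables, and `manifest.json` with
per-file checksums.

## Known limitations

* No consensus clustering or automatic `k` selection; `k` is the user's
  scientific choice.
* Raw `p < 0.05` allocation (by design, to mirror the candidate-gene
  tradition) inflates set sizes under many candidates; use the BH option
  when the candidate list is long.
* Cross-platform handling is symbol intersection plus within-cohort
  re-normalization only.
* The control class in validation is handled by clustering at `k+1` and
  Euclidean geometry, or by an externally supplied control model; a
  COPD-only discovery model cannot itself predict "control".
* Enrichment conclusions inherit the arbitrariness of the background
  universe; the default (genes present in data ∩ annotation) is stated,
  not sacred.
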