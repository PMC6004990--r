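# copdsubtype

Molecular subtyping of chronic obstructive pulmonary disease (COPD)
expression cohorts, for researchers who have a gene-by-sample expression
table, a curated candidate-gene list, a pathway annotation (GMT) and
clinical spirometry, and want a reproducible, tested pipeline from
clustering to cross-cohort validation.

## What it computes

Given candidate-gene expression (z-normalized per gene), the pipeline:

1. **Discovers subtypes** by average-linkage (UPGMA) hierarchical
   clustering of samples under correlation distance `d = 1 − r` (Euclidean
   optional), assessed by the cophenetic correlation coefficient and cut
   into `k` subtypes with reproducible size-ordered labels.
2. **Allocates genes** to subtypes by two-sided Welch t-tests of each
   subtype against the rest (`p < α`, default 0.05); a gene may belong to
   several subtype sets, and is flagged *primary* where its |t| is
   largest. The cross-subtype intersection gives the common genes.
3. **Enriches pathways** per subtype with the one-sided Fisher's exact
   test (BH-adjusted), partitions pathways into common and
   subtype-unique, and scores each pathway's deviation in each subtype:

   A(P) = (1/N) Σᵢ (X̄ᵢ − Ȳᵢ)²

   over the N allocated genes of pathway P, where X̄ᵢ is gene i's mean in
   the subtype and Ȳᵢ its mean over all samples.
4. **Tests clinical indicators** (FEV1, FEV1/FVC, age by one-way ANOVA;
   sex by chi-square) across subtypes.
5. **Trains one-vs-rest linear SVMs** (C = 1) on per-sample pathway
   deviation features dₛ(P) = (1/N) Σᵢ (xᵢₛ − Ȳᵢ)², evaluated by
   stratified 5-fold cross-validated ROC/AUC.
6. **Validates across cohorts**: shared-gene harmonization, independent
   clustering of the validation cohort, a predicted-vs-clustered confusion
   matrix with per-class consistency ratios (diagonal / column total), and
   permutation p-values for those ratios (default 10,000 label
   permutations).

A synthetic-cohort generator (`synth_config()` / `generate_cohort()`)
plants known subtype structure, pathway enrichment and subtype-correlated
clinical covariates so the whole pipeline is testable offline; see the
methods vignette (`vignettes/copd-subtyping.Rmd`) for the model and every
design decision.

## Worked example

```r
library(copdsubtype)

cfg <- synth_config(seed = 1)          # 2000 genes, 213 candidates, 229 samples
coh <- generate_cohort(cfg)
z    <- zscore_rows(coh$expression)$matrix
cand <- subset_to_candidates(z, coh$truth$candidate_genes)

asg <- discover_subtypes(cand, k = 3)
asg
#> Subtype assignment: 229 samples in 3 subtypes
#> subtype
#>  1  2  3
#> 98 78 53
#> Cophenetic correlation coefficient: 0.981
```

The 229 samples split into subtypes of 98/78/53 (labels are numbered by
decreasing size), and the cophenetic coefficient 0.981 says the dendrogram
reproduces the pairwise distances almost perfectly — expected here, since
the generator plants well-separated subtypes.

```r
alloc <- allocate_genes(differential_t_test(cand, asg))
lengths(alloc$sets)                    # genes allocated per subtype
#> subtype1 subtype2 subtype3
#>      162      164      163
length(alloc$common)                   # in all three subtypes
#> [1] 160
```

Per-subtype sets overlap heavily (z-scored data: elevation in one subtype
depresses the rest), hence 160 of ~163 genes are shared; the *primary*
flag records each gene's strongest subtype.

```r
pw  <- generate_pathway_annotation(cfg, rownames(z), coh$truth$informative_genes)
uni <- intersect(rownames(z), unique(unlist(pw)))
rec <- lapply(alloc$sets, function(s) fisher_enrichment(intersect(s, uni), pw, uni))
parts <- partition_pathways(rec)        # 25 pathways common to all subtypes
dev <- deviation_score_table(cand, asg, pw[parts$common], alloc$sets)
head(dev, 3)
#>   pathway subtype  N         A
#> 1  PW0001       1 28 0.5436315
#> 2  PW0001       2 28 0.7018419
#> 3  PW0001       3 28 0.8237622

schema <- deviation_feature_schema(pw[parts$common], alloc$primary_sets, dev)
feats  <- sample_deviation_features(cand, schema, rowMeans(cand))
cross_validate_roc(feats, asg, folds = 5, seed = 1)
#> Cross-validated one-vs-rest SVM (5-fold, seed 1)
#>   subtype 1: AUC = 1, accuracy = 1
#>   subtype 2: AUC = 1, accuracy = 1
#>   subtype 3: AUC = 1, accuracy = 1
#>   overall argmax accuracy = 1
```

Deviation scores quantify how far each subtype's pathway expression sits
from the cohort mean (0 = no deviation); on this planted cohort the
pathway features separate the subtypes perfectly. Clinical testing on the
same run finds the planted lung-function gradient
(`clinical_association_table(coh$clinical, asg)` reports FEV1/FVC ANOVA
p ≈ 3e-06 and a sex imbalance p ≈ 4e-04) while shared-distribution age is
non-significant.

The same stages run from files in one call — `pipeline_config()` +
`run_pipeline()` — writing every table, the serialized SVM
(`svm_model.json`) and a checksummed `manifest.json` to an output
directory; reruns with the same seed are byte-identical.

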