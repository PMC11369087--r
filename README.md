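# ampfeatr

Feature engineering for AMPylation-site prediction from peptide sequences.

AMPylation is a post-translational modification in which an AMP group is
attached to a protein residue, primarily threonine or tyrosine. Predicting
whether a candidate site is AMPylated from its sequence context — a
31-residue window, 15 residues either side of the site — is a binary
classification problem whose difficulty lives almost entirely in the
featurization of the raw amino-acid string. `ampfeatr` is for
computational biologists building such site predictors (for AMPylation or
other PTMs): it turns peptide windows into classifier-ready numerical
features, evaluates standard classifiers over feature configurations, and
explains the fitted models.

## The framework

A configuration is a triple of lists:

1. **Representations** — alphabets the sequence is re-encoded under:
   `no_reduction` (the 20 amino acids), `hydro` (5 Kyte–Doolittle
   hydropathy groups `H_1`..`H_5`), `conform` (7
   conformational-similarity groups `C_1`..`C_7`), or any user grouping
   given as a TSV mapping file.
2. **Feature families** — per representation: `counts` (normalized
   monogram composition, *k* values), `mat` (flattened normalized
   co-occurrence matrix of symbol pairs at offset δ, *k*² values per
   offset), `tfeat` (five texture statistics of that matrix — energy,
   entropy, homogeneity, contrast, dissimilarity — per offset), and
   `pro2vec` (skip-gram n-gram sequence embeddings; 50 dimensions on the
   standard alphabet, 300 on reduced ones).
3. **Offsets** — the positional gaps δ at which symbol pairs are counted;
   `counts` and `pro2vec` are offset-independent.

For a sequence *S* over *k* symbols, the monogram vector is
C[j] = count(p_j)/n; the offset-δ co-occurrence matrix is
G<sup>δ</sup>_ij = count(a_t = p_i, a_{t+δ} = p_j) / (n − δ); texture
statistics are e.g. Energy = Σ G², Entropy = −Σ G log₂(G + ε). All
selected blocks are concatenated under deterministic feature names
(`K`, `H_2H_2(1)`, `hydro:entropy(3)`, ...), so the configuration
(`no_reduction`+`hydro`, `counts`+`tfeat`, offsets {1,3}) yields
20 + 5 + 2·2·5 = 45 named features.

Around the featurizer the package provides stratified k-fold
cross-validation of five classifiers (ridge logistic regression, RBF SVM,
a small neural network, random forest, gradient-boosted trees) with
accuracy / precision / recall / F1 / MCC / AUC-ROC; exact
(subset-enumeration) and permutation-sampled Shapley explanations with
waterfall, scatter and global-importance exports; FASTA/CSV peptide I/O,
31-mer window extraction, X-padding filters; a seeded synthetic dataset
generator; and a command line (`inst/cli/ampfeat.R`) with `simulate`,
`extract`, `dims`, `cv`, `grid` and `explain` subcommands.

## Worked example

```r
library(ampfeatr)

# a seeded synthetic dataset at the curated study's scale (153 positive /
# 250 negative 31-mers) with a planted lysine-composition signal
peps <- generate_synthetic(153, 250, composition_shift = c(K = 1.5), seed = 42)

spec <- feature_spec(c("no_reduction", "hydro"), c("counts", "tfeat"), c(1, 3))
spec
#> <feature_spec>
#>   representations: no_reduction, hydro
#>   feature types:   counts, tfeat
#>   offsets:         1, 3
#>   dimension:       45

fm <- extract_matrix(peps, spec)
round(fm$x[1, c("K", "T", "H_1", "hydro:entropy(1)")], 4)
#>                K                T              H_1 hydro:entropy(1)
#>           0.1290           0.0645           0.4194           3.6314

run_cv(peps, spec, "rf", k = 10, seed = 1)
#> <eval_report> rf - 10 folds, seed 1
#>  accuracy precision    recall        f1       mcc   auc_roc
#>    0.9231    0.9279    0.8696    0.8946    0.8388    0.9574
```

The first peptide is 12.9% lysine (the planted enrichment at work), 41.9%
of its residues fall in the hydrophilic group `H_1`, and its
adjacent-pair hydropathy texture has entropy 3.63 bits. Ten-fold
cross-validated random forest separates the planted signal almost
perfectly (AUC 0.96) — a check of the machinery, not a biological claim.

Shapley explanation of a fitted model:

```r
test <- train_test_split(peps$label, 0.2, seed = 1)
x_tr <- extract_matrix(peps[!test, ], spec)$x
fit  <- ampfeatr:::fit_model("rf", x_tr, peps$label[!test], seed = 1)
ex   <- explain_instances(function(z) ampfeatr:::predict_prob(fit, z),
                          extract_matrix(peps[test, ], spec)$x[1:5, ],
                          x_tr, seed = 1)
head(global_importance(ex))
```

Every explanation satisfies local accuracy: base value + Σφ = prediction.

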