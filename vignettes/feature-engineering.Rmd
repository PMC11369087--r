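---
title: "Feature engineering for AMPylation-site prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature engineering for AMPylation-site prediction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampfeatr)
```

## The problem

AMPylation is a post-translational modification in which an adenosine
monophosphate group is attached to a protein residue — primarily threonine
and tyrosine. Experimentally mapping AMPylation sites is slow and
expensive, so a common strategy is to train a binary classifier that looks
at a fixed window of sequence context around a candidate residue (here,
15 residues on each side, a 31-mer) and predicts whether the centre
residue is modified. The predictive power of such classifiers depends
almost entirely on how the raw amino-acid string is turned into numbers.
`ampfeatr` implements a combinatorial feature-engineering framework for
exactly that step, together with the evaluation and explanation machinery
needed to use it.

## Sequence representations

A *representation* is an alphabet: a symbol set plus a total mapping from
the 20 standard amino acids onto it.

* `no_reduction` — the identity, 20 symbols.
* `hydro` — 5 hydropathy groups `H_1`..`H_5`. We bin the raw
  Kyte–Doolittle hydropathy scale (range −4.5 to 4.5) into five
  equal-width bins of width 1.8, ordered hydrophilic → hydrophobic:
  `H_1` = RKNDQEH, `H_2` = PY, `H_3` = WSTG, `H_4` = AMC, `H_5` = FLVI.
* `conform` — 7 conformational-similarity groups `C_1`..`C_7` in the
  spirit of the Pal–Chakrabarti side-chain/main-chain conformational
  analysis: a large helix-compatible group (AEHKLMQR), singletons for the
  conformationally idiosyncratic residues C, G, P and S, the amide/acid
  pair DN, and the β-branched/aromatic group FITVWY.

Published reduced-alphabet schemes differ in their exact assignments, and
the groupings in the literature on which these defaults are based are not
uniquely determined by group counts alone. The two packaged tables are
therefore plain TSV files (`inst/extdata/alphabets/`), and any alternative
grouping can be supplied as a user mapping file to `load_alphabet()`; all
downstream code is agnostic to the assignment and only the group counts
(5 and 7) affect feature dimensions. Reduction is position-wise, so
sequence length is always preserved, and sequences containing anything
outside the 20 standard letters (including the `X` padding residue) are
rejected with a position-level error rather than silently recoded.

## Feature families

For a represented sequence $S = [a_1, \dots, a_n]$ over $k$ symbols:

**Monogram counts** (`counts`, $k$ values). The count of each symbol
divided by $n$; the classical amino-acid (or reduced-group) composition.

**Offset bigram counts** (`mat`, $k^2$ values per offset). For offset
$\delta \ge 1$, the matrix $G^{\delta}_{ij}$ counts pairs
$(a_t = p_i, a_{t+\delta} = p_j)$ over $t = 1..n-\delta$, normalized by
the total pair count $n - \delta$, then flattened row-major. $\delta = 1$
is ordinary dipeptide composition; larger offsets capture gapped residue
relationships. A sequence shorter than $\delta + 1$ has no pairs; we
return the all-zero matrix rather than erroring so that a dataset of mixed
lengths still yields constant-width features. No pseudo-counts are added.

**Texture statistics** (`tfeat`, 5 values per offset). Five scalar
summaries of the normalized co-occurrence matrix, borrowed from gray-level
co-occurrence texture analysis: energy $\sum G^2$, entropy
$-\sum G \log_2 (G + \varepsilon)$, homogeneity $\sum G / (1 + (i-j)^2)$,
contrast $\sum (i-j)^2 G$ and dissimilarity $\sum |i-j| \, G$. The
entropy guard $\varepsilon$ is unspecified in the texture literature's
usual presentation; we fix $\varepsilon = 10^{-12}$, which is negligible
against the smallest possible nonzero entry of a normalized matrix
($\ge 1/400$ for the configurations shipped) yet avoids $\log 0$. The
index origin for $(i-j)$ is 1-based; only differences enter, so the
choice is cosmetic but fixed.

**Sequence embeddings** (`pro2vec`, one block per representation).
Skip-gram word2vec embeddings of n-gram "words" ($n = 3$ by default, the
ProtVec convention). Training documents are the $n$ shifted
non-overlapping n-gram tilings of each training sequence; a sequence is
embedded as the sum of the vectors of all its *overlapping* n-grams.
Default dimensions are 50 on the standard alphabet and 300 on reduced
alphabets. Because no word2vec implementation is available as an R
package, the trainer is implemented in the package itself: single-threaded
SGD with negative sampling (5 negatives, unigram$^{3/4}$ noise
distribution, window 5, 10 epochs, linearly decaying learning rate from
0.025), which makes training exactly reproducible for a given seed. The
training corpus defaults to the dataset at hand (hundreds of 31-mers) —
desk scale rather than the millions of sequences behind published
pretrained protein embeddings — so absolute embedding quality is modest;
the word2vec text format loader (`read_word2vec()`) accepts externally
trained vectors when stronger embeddings are wanted.
Out-of-vocabulary n-grams contribute zero vectors and are counted, so
embedding width never varies. `min_count` defaults to 1 so that small
corpora remain fully covered.

## The assembly framework

A configuration is the triple (representations, feature families,
offsets). The assembled width is

$$ D = \sum_{r} \Big[ k_r \,[\text{counts}] + |\Delta|\, k_r^2\,[\text{mat}]
 + 5\,|\Delta|\,[\text{tfeat}] + d_r\,[\text{pro2vec}] \Big] $$

with $k_r$ the alphabet size and $d_r$ the embedding dimension of
representation $r$. `counts` and `pro2vec` are offset-independent — the
package enforces this rather than trusting callers. The worked examples:
(`no_reduction`+`hydro`, `counts`+`tfeat`, offsets 1,3) gives
$20 + 5 + 4 \times 5 = 45$ features; all three representations with
`counts`+`mat` at offsets 1,3 give
$(20+5+7) + 2\,(400+25+49) = 980$.

Feature names are deterministic: bare symbols for monograms (`K`,
`H_2`), `AB(δ)` for bigrams (`H_2H_2(1)`), `rep:stat(δ)` for texture,
`rep:p2v_i` for embedding components. Concatenation order is
representation-major, then family in the fixed order counts → mat →
tfeat → pro2vec, then offset, then within-block canonical order. No
published ordering exists for these blocks and all shipped classifiers
are permutation-invariant in their inputs, so any fixed order is
equivalent; ours is documented and stable, and extraction is a pure
function of (sequence, configuration, models).

## Data handling and the synthetic generator

Windows are extracted as `protein[site − 15 .. site + 15]`; sites closer
than 15 residues to a terminus are *rejected*, not padded — mirroring a
curated dataset from which X-padded windows were removed — and
`filter_padded()` drops any record still containing `X`. I/O supports
FASTA (label carried as a `label=0|1` description token) and CSV.

The synthetic generator emulates the *shape* of the curated AMPylation
dataset (fixed-length 31-mers, binary label, an approximately 153:250
class ratio at full scale) without claiming its biology. Negatives are
i.i.d. draws from Swiss-Prot-like background residue frequencies.
Positives optionally (and by default) centre on T or Y, the primary
AMPylation target residues, and can carry a per-residue log-odds
composition tilt and/or an exact planted motif. What the generator does
*not* emulate: real positional motifs around sites, phylogenetic
redundancy, protein-level grouping between windows, and class-dependent
higher-order structure. Tests passing on synthetic data therefore
demonstrate the correctness and statistical sanity of the machinery (no
leakage, null behaviour, signal recovery), not field performance on
curated AMPylation data.

## Evaluation

Stratified k-fold cross-validation (default $k = 10$) deals each class
round-robin after a seeded shuffle, so per-fold class counts deviate from
the global ratio by at most one instance. Metrics are computed literally
from confusion counts at a 0.5 probability threshold — accuracy,
precision, recall, F1, MCC — plus AUC-ROC in its Mann–Whitney form (ties
count one half). Degenerate denominators (e.g. no predicted positives)
define the affected metric as 0 and are flagged, a choice the metric
formulas themselves leave open. Aggregates are fold means.

Classifiers run at their library defaults with seeded fits: ridge
logistic regression (glmnet, fixed $\lambda = 1/n$, the analogue of an
L2 penalty with $C = 1$; unpenalized fitting is ill-posed for the
$p \gg n$ configurations), RBF-kernel SVM with Platt-scaled probabilities
(e1071), a single-hidden-layer neural network with hidden width
$\min(10, \lceil p/2 \rceil)$ and sigmoid output (nnet) — the "capped at
10 or half the input size" rule read as a minimum, the conservative
interpretation — random forest (randomForest, probabilities as vote
fractions), and gradient-boosted trees (xgboost, 100 rounds). LightGBM
has no R implementation available, so the model set stops at these five.
When a configuration includes `pro2vec`, embedding models are retrained
per fold on the training folds' sequences only; nothing fitted ever sees
held-out data.

## Shapley explanations

Model predictions (predicted probabilities) are attributed to features
with Shapley values. The coalition value $v(S)$ fixes the features in $S$
at the explained instance and averages the model over an explicit
background sample for the rest (interventional marginalization;
background defaults to the training split, capped at 100 seeded rows).
`exact_shapley()` enumerates all $2^d$ coalitions with the combinatorial
weights $|S|!\,(d-|S|-1)!/d!$ — exact but exponential, so it refuses
$d > 16$ and serves as the verification path. `sampled_shapley()` is the
permutation-sampling estimator for wide feature sets; its Monte-Carlo
residual is spread uniformly across features so the efficiency identity
$\phi_0 + \sum_i \phi_i = f(x)$ holds exactly (the residual magnitude is
retained for inspection). Exactness of the subset form is tested against
an independent all-orderings oracle. Global importance is the mean
absolute contribution per feature; exports are tables (per-instance
waterfalls with cumulative sums, and per-feature value/contribution
scatter pairs), not rendered plots.

## Numerical and scale choices

Test and example problem sizes are deliberately desk-scale: corpora of
tens of 31-mers for embedding tests, a few hundred instances for CV
tests, and 1000 instances for the null-AUC property check — large enough
for the statistical assertions (|AUC − 0.5| < 0.05 under the null) to be
stable across seeds, small enough to keep the full suite fast on one
CPU. The 153/250 class-size default of the generator reproduces the
curated dataset's scale. All randomness — generator, folds, model fits,
embedding training, background subsampling — flows from explicit integer
seeds.

## Known limitations

* The packaged reduced-alphabet assignments are defensible defaults, not
  the unique published groupings; swap in your own TSV when fidelity to a
  specific scheme matters.
* The in-package skip-gram trainer is exact and reproducible but not
  fast; for corpora beyond a few thousand documents, train externally and
  load through `read_word2vec()`.
* Exact Shapley enumeration is exponential; wide configurations (hundreds
  of features) go through the permutation sampler, whose per-feature
  values carry Monte-Carlo error even though their sum is exact.
* Synthetic data validates machinery, not biology: performance numbers on
  generated datasets say nothing about performance on curated AMPylation
  sites.
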