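---
title: "Signed cause-effect embeddings: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed cause-effect embeddings: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalembed)
```

## The data model

The package works with curated *signed causal relationships*. An edge
A &rarr; B with sign +1 states that activating A increases B; sign &minus;1
that it decreases B; the absence of an edge encodes "no known effect".
Two edge families matter:

* **expression edges** connecting `N` regulators (genes, optionally drugs)
  to the `M` target genes whose expression they causally change, collected
  in the sign matrix `s` (entries in {-1, 0, +1});
* **gene-function edges** connecting genes to biological functions and
  diseases, collected in `Y` (same coding). Functions live in a hierarchy
  in which parents inherit the signed associations of their descendants
  (`propagate_ontology()`), except for very general terms the user lists in
  `excluded_roots`.

Two readers' rules are worth calling out because they shape everything
downstream. First, duplicate expression edges with conflicting signs are
*dropped*: stored signs are consensus calls, and without per-finding counts
there is no principled majority vote (`0` is the conservative choice). The
same rule applies when ontology descendants disagree about a gene: the
parent entry becomes 0. Second, all entity orderings are lexicographic
(under the C collation), so matrices are bytewise reproducible across
platforms and locales.

## Gene embeddings

All three embedding strategies start from the row-normalized signed
bi-adjacency matrix

$$W_{ij} = \frac{s_{ij}}{\sqrt{N_i}}, \qquad N_i = \sum_j |s_{ij}|,$$

whose rows are unit vectors, so the gene-gene similarity $S = W W^T$ has
unit diagonal; $S_{ik}$ is +1 for identical downstream sign patterns,
&minus;1 for opposite patterns, and 0 for disjoint target sets. (The
$1/\sqrt{N_i}$ is forced by requiring $\operatorname{diag}(S) = 1$; a
$1/N_i$ normalization would not satisfy it.)

**E1 (spectral).** The truncated SVD $W \approx U \Sigma V^T$ with the top
`K` singular triplets; rows of `U` are the embedding vectors and
$U^T U = I$. Columns of `U` are eigenvectors of `S`. The implementation
uses a dense LAPACK SVD — exact and fast at the scales this package
targets (up to a few thousand regulators); each column of `U` is oriented
so its largest-magnitude entry is positive, a pure serialization
convention to which every downstream score is invariant. Singular values
beyond the numerical rank are reported as zero with a warning. Within a
degenerate singular subspace the solver's basis is accepted as is.

**E2 (neural).** A bottleneck network: one-hot input &rarr; linear layer
without bias to `K` dimensions (the embedding), &rarr; linear layer with
bias + ReLU to a hidden layer (`hidden = 1000` by default — widening it
or adding layers changes little), &rarr; linear output without bias, trained with
MSE against the rows of `W`. Because no bias follows the embedding, the
*linear part* of the reconstruction is exactly antisymmetric in the
embedding vector — negating a gene's vector negates its predicted
downstream effect, the symmetry that makes signed scoring meaningful.
Optimizer details are independent of the architecture and are declared
here: full-batch Adam (rate $10^{-3}$ by default), early stopping
on a 50-epoch loss plateau, Gaussian fan-in initialization, all
configurable and reproducible from `seed`. An `activation = "identity"`
switch turns the decoder linear; in that regime the optimum provably
coincides with the spectral rank-`K` solution up to an invertible linear
map, which the regression of the next section absorbs.

**E3 (graph).** A signed coregulation graph `H` joins regulators whose
sign patterns agree or disagree more than chance:

$$z_{ik} = \frac{\sum_j s_{ij} s_{kj}}{\sqrt{N_{ik}}}, \qquad
N_{ik} = \sum_j |s_{ij}||s_{kj}|,$$

an edge being kept when $|z_{ik}| \ge 1.5$ by default. The
$1/\sqrt{N_{ik}}$ gives the statistic unit variance under a random-sign
null, which is what makes it a z-score; larger cutoffs were reported to
lower accuracy. Signs are then encoded *losslessly* into an unsigned graph
by doubling every node into `u`/`v` replicas: positive edges connect
replicas in parallel, negative edges crosswise. node2vec-style random
walks (length 30, 100 per node, `p = q = 1`, i.e. uniform first-order
walks) feed a skip-gram model with negative sampling (window 10, 5
negatives, 5 epochs — the cited implementation's defaults). The
`u`-replica vectors are returned; the replicas are symmetric by
construction, and the `v` matrix is kept for diagnostics such as the
anti-similarity check (a gene connected to another only by a negative edge
co-occurs with the *other replica*). Genes isolated at the cutoff get no
embedding and are excluded from scoring with a logged count. Walks and
skip-gram run in compiled code with a single-threaded, integer-seeded RNG,
so results are bit-reproducible.

## Function embeddings, scores and thresholds

Each function `j` is embedded by ridge-free least squares,
$p_j = (U^T U)^{-1} U^T y_j$ (for orthonormal E1 simply $U^T y_j$; both
paths agree to $10^{-10}$ and the general path refuses numerically
singular $U^T U$, advising a lower `K`). Vectors are normalized,
$\tilde p_j = p_j / \lVert p_j \rVert$, so that isotropic noise produces
the same score distribution for every function; all-zero columns are
flagged and excluded.

The gene-function score is $s_{ij} = \tilde p_j \cdot x_i$ — positive for
predicted activation, negative for inhibition, exactly antisymmetric under
negation of either vector. Scores are standardized against the isotropic
null: a random unit $\tilde p$ gives $s$ with standard deviation
$\lVert x_i \rVert / \sqrt{K}$, hence

$$z_{ij} = \frac{s_{ij}\sqrt{K}}{\lVert x_i \rVert}.$$

This analytic transform is a design decision of this package; an
empirical per-function column standardization is available via
`zmethod = "empirical"`. The Monte-Carlo null check in the test suite
confirms the analytic z is standard normal for random unit function
vectors.

Function-function similarity is the cosine of normalized vectors. For two
random unit vectors in `K` dimensions the cosine has standard deviation
$\sigma_c = K^{-1/2}$ (from $1 = K\sigma_c^2$), so the significance
threshold at two standard deviations is $2K^{-1/2}$ —
`r round(similarity_threshold(500), 2)` at the typical `K = 500`, which is
what `similarity_threshold()` returns and the acceptance script reports.

Latent linear structure ("process of context" analogies) is probed by
projecting selected function vectors on their top two principal components
(mean-centered, never variance-scaled — the vectors are already unit
length; the normalized vectors are used) and testing whether segments joining
same-context pairs are parallel: the observed circular spread of segment
angles (taken modulo $\pi$, undirected) is compared against permutations
of the segment endpoints, with $p = (1 + \#\{SD_{perm} \le SD_{obs}\}) /
(1 + n_{perm})$. Coincident endpoints are dropped with a warning;
permutations are pure (without replacement). The disease map reduces
disease vectors to 20 principal components (exact, oracle-tested) and lays
them out with a compact exact-gradient t-SNE written for this package
(seed-controlled; smoke-tested only, as any stochastic layout should be).

## Cross-validation

Balanced masking: per replicate, `n` entries with $Y = +1$, `n` with
$Y = -1$ and `2n` zeros are drawn from functions that are hierarchy
*leaves* supported by at least 10 genes (so inheritance cannot leak masked
information upward); zeros are drawn uniformly over eligible cells (the declared sampling
choice; per-function balancing of zeros would be the alternative). The masked entries are set to
0, the regression refit, and the masked cells scored. Gene embeddings are
*not* refit: they depend only on the expression graph, which masking does
not touch, so refitting them would be wasted work with an identical
result. Task 1 (absolute prediction) thresholds $|s|$ over all `4n`
entries; task 2 (sign prediction) uses the signed score on the `2n`
nonzero entries, and its ROC flips into the complementary task's ROC
exactly. Replicates are drawn independently (they may overlap), matching
"k independent test sets". Metrics are the trapezoidal AUC and the
precision at the smallest achieved recall of at least 5%, with tied scores
crossing thresholds together; curves are averaged vertically on a fixed
101-point grid (the averaging grid is unspecified in the source; linear
interpolation on recall/FPR is the declared choice). Zeros are treated as
negatives without correction — the handful of false negatives among them
is assumed not to move the metrics. The defaults `n = 1000`, `k = 50`
suit curated-content scale; synthetic-scale runs
in the tests use proportionally smaller `n` and `k` (stated below).

## Disease networks

For a disease, the top 15 genes by $|z|$ (ties broken lexicographically)
and the top 20 functions by absolute cosine similarity are selected; a
candidate function is dropped when it is an ontology ancestor of a
higher-ranked retained candidate (specificity), only the best scorer per
context bundle survives (redundancy), and the disease itself and its
ancestors are excluded. The function-disease ranking instrument is the
cosine similarity, the same tool used for function-function relations. Edges require $|z_{ij}| > 3$ *and* sign consistency
$\operatorname{sign}(z_{ij}) = \operatorname{sign}(g_i)\,
\operatorname{sign}(f_j)$; they carry `known`/`inferred` provenance from
`Y`, and gene nodes record whether the disease association itself was
curated. Negating the disease vector flips every node sign and leaves the
edge set unchanged — an exact symmetry the tests assert. No additional
score floor is applied to the top genes beyond the top-15 rank.

## Drugs

Drugs enter the expression graph as extra regulator rows and flow through
the identical pipeline (unit-norm rows included). The drug-disease
predictor is an MLP with one hidden layer of 200 nodes on drug embedding
features, binary cross-entropy loss, balanced negative draws from the
remaining drugs, a 70/30 split, and repeated train/test runs with averaged
curves. Optimizer (full-batch Adam), L2 decay 0.01, per-split feature
standardization, and per-repeat refreshed negatives are declared choices
of this package. Negative pools exclude only the disease's own positives.

## The synthetic generator

Every downstream stage is exercised on data with *planted structure*:
genes, targets, functions and drugs receive i.i.d. standard-normal latent
vectors in `d` dimensions; expression edges appear with probability
`density` and carry sign $\operatorname{sign}(g_i \cdot t_j + b)$, where
the scalar offset `b` is the exact 1/3-quantile of the realized
dot-product distribution, calibrating the positive:negative sign ratio to
2:1 (the imbalance typical of curated content); signs flip independently
with probability `noise_rate`. Function columns mark the
`genes_per_function` genes with the largest $|g_i \cdot f_j|$ with
$\operatorname{sign}(g_i \cdot f_j)$; drug-disease labels mark drugs whose
affinity to a disease vector exceeds its 80%-quantile threshold. A
latent-factor model was chosen over, say, a stochastic block model because
E1/E2 assume low-rank structure in `W`, which makes parameter recovery a
meaningful test. Everything is a pure function of an integer seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real curated content: literature citation structure,
per-edge finding bundles, hub-dominated degree distributions, the
hierarchy-induced correlation between function columns, or any biological
ontology semantics. Tests on this generator demonstrate that the
*algorithms* recover planted signal, not that curated knowledge graphs
have that signal.

**Known quantitative ceilings at desk scale.** Two deserve emphasis
because they bound what recovery tests can achieve:

* The unit-norm rows of `W` erase gene *magnitude* — only the latent
  direction survives. Planted associations and drug labels, however,
  select by raw affinity $|g_i \cdot f_j|$, which depends on
  $\lVert g_i \rVert$. At the study conditions used in the acceptance
  suite (N = 500, M = 2000, d = 10, density 0.05, noise 0, K = 25,
  n = 50, k = 10), even an oracle that knows the true target vectors and
  fits each gene's direction from its realized signed row stays at the
  edge of an absolute-prediction AUC of about 0.9, and the embedding
  necessarily lands below it; precision at 5% recall does clear 0.9, and
  accuracy degrades monotonically in the noise rate. The corresponding
  test block states the full bars and is expected to flag the AUC
  sub-assertion at this scale.
* The drug MLP learns from only ~28 balanced training drugs at the
  default synthetic scale (100 drugs, 20% positive rate); with the
  embedding's direction-recovery noise, repeat-averaged AUC lands well
  above chance but below the level reachable with either more drugs or
  noiseless features. The shuffled-label control sits at chance, as it
  must.
* At small `N`, the ReLU decoder of E2 has more capacity than data: it
  reconstructs `W` beyond the linear optimum through a nonlinearly coded
  embedding that linear regression cannot exploit, so the E1-E2
  cross-validation equivalence expected at curated-content scale is
  demonstrated here in the provable linear regime
  (`activation = "identity"`) and only the in-sample score separation is
  asserted for the ReLU default.

## Numerical choices and problem sizes

Dense SVD tolerance follows LAPACK; orthonormality is asserted to
$10^{-8}$, least-squares agreement to $10^{-10}$, exact antisymmetries to
$10^{-12}$. Unit tests run on instances of roughly 12-300 regulators,
25-1000 targets and 8-40 functions; the acceptance block uses
N = 500 / M = 2000 / K = 25 with k = 10 replicates of n = 50, and the
drug block 100 drugs with 25 repeats. These sizes were chosen so the whole
suite completes in about a minute while keeping binomial/permutation
tolerances (3-sigma bands, Kolmogorov-Smirnov at $10^4$-$10^5$ draws)
meaningful.
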