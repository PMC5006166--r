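---
title: "Disease and gene embeddings from discharge records: models, evaluation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease and gene embeddings from discharge records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgembed)
```

## The model

An inpatient discharge record is an ordered list of diagnosis codes,
$d^{(i)} = (d_1, \dots, d_{M_i})$, ordered by importance for the admission.
`dgembed` treats each record as a sentence and each diagnosis as a word,
and learns a $D$-dimensional vector $v_d$ for every disease by maximizing
the skip-gram log-likelihood

$$
\mathcal{L} \;=\; \sum_{i} \sum_{m=1}^{M_i} \sum_{\substack{-b \le j \le b \\ j \ne 0}}
\log P(d_{m+j} \mid d_m),
\qquad
P(d_c \mid d_m) \;=\;
\frac{\exp\left({v'_{d_c}}^{\top} v_{d_m}\right)}
     {\sum_{d \in \mathcal{D}} \exp\left({v'_d}^{\top} v_{d_m}\right)},
$$

with separate *input* ($v$) and *output* ($v'$) vectors and a context
half-window of $b$ positions truncated at record boundaries (`train_d2d()`,
the disease-only model). Diseases that co-occur, or that occur in similar
company, end up close in cosine similarity even if they are never seen in
the same patient.

The joint model (`train_dag2d()`) folds in curated disease–gene
associations: when the central disease $d_m$ carries genes
$G_{d_m} = \{g_1, \dots, g_{N_m}\}$, each gene also predicts the context,

$$
\mathcal{L}' \;=\; \sum_i \sum_m \sum_{j}
\Big[ \log P(d_{m+j} \mid d_m) + \sum_{g \in G_{d_m}} \log P(d_{m+j} \mid g) \Big],
$$

so genes receive vectors in the same space as diseases and disease–gene
association discovery becomes a nearest-neighbour query restricted to gene
tokens. The predicted token is always a *disease*: genes appear only as
centers, never as softmax outputs, which is why the negative-sampling noise
distribution puts zero mass on gene tokens.

Both objectives are optimized by stochastic gradient ascent on the
negative-sampling surrogate: each observed (center, context) pair
contributes $\log\sigma({v'_c}^\top v) + \sum_{k=1}^{25}
\log\sigma(-{v'_{n_k}}^\top v)$ with negatives drawn from the unigram
distribution raised to the $3/4$ power. An exact-softmax oracle
(`exact_log_likelihood()`) is provided for small instances (vocabulary
$\le$ 5000) and is used by the tests to check normalization, the
empty-gene-map reduction, and gene-order invariance; it is never the
training path.

## Parameters that matter

* `D` (default 200): embedding dimension. Precision@K saturates near 200 in
  the regime the defaults target; the bundled experiments use 50, which is
  ample for a 200-disease synthetic vocabulary.
* `b` (default 8, positions): half-window, chosen close to the mean record
  length of 7.58 diagnoses so that most windows span the whole record. The
  window is *fixed* (no random shrinking); it only truncates at record
  boundaries.
* `negatives` (default 25): noise samples per update. A negative that
  collides with the positive target is redrawn (up to 100 attempts, then
  the update is dropped with a warning).
* `subsample_t` (default 1e-3): center occurrences of a token with corpus
  frequency $f$ are kept with probability $\min(1, \sqrt{t/f})$. This is
  applied to diseases *and* genes; a gene's frequency is the occurrence
  frequency of its host diseases. Subsampling here skips the *center* role
  only — a skipped occurrence still serves as context for its neighbours,
  which is a deliberately simpler rule than dropping the token from the
  sentence.
* `lr_initial`/`lr_final` (0.025 to 1e-4): linear decay over the total
  number of scheduled context pairs (epochs x pairs), advanced whether or
  not a pair is subsampled away, so the schedule is data-dependent but not
  randomness-dependent.
* `min_count` (default 5): vocabulary floor for diseases. Genes attached to
  a retained disease inherit at least that count (their count is the summed
  count of their hosts), so the floor never needs a second knob.
* `epochs` (default 5) and `seed`: one integer seed drives initialization,
  subsampling, gene-bag shuffling and negative sampling through a
  self-contained counter RNG in the compiled core, making training
  bit-for-bit reproducible for a given configuration — independently of
  R's RNG state.

Initialization is the standard one for this model family: input vectors
uniform in $(-0.5/D, +0.5/D)$, output vectors zero. The released
representation of a token is its input vector.

Gene bags are re-shuffled at every center occurrence. The objective is
invariant to gene order (the inner sum is over a set), but shuffling
removes any ordering bias carried over from the source association tables;
update order within a center is disease first, then genes in shuffled
order, purely for reproducibility.

## Evaluation protocols

*Phenotyping.* For each query disease with gene annotations, the $K$
nearest annotated diseases are retrieved by cosine; a neighbour is positive
when it shares at least one gene with the query. We report average
precision@K and the average gene-set overlap@K. The candidate pool defaults
to annotated diseases because a neighbour without annotations can never be
labelled positive — ranking against unannotated diseases would conflate
embedding quality with annotation coverage (an `"all"` mode exists). The
overlap normalizer is Jaccard, $|G_q \cap G_n| / |G_q \cup G_n|$: it is
symmetric and bounded in $[0,1]$; the asymmetric $|G_q \cap G_n|/|G_q|$
variant is available behind `normalizer = "query"`.

*Gene discovery.* A uniform 20% of annotated diseases have their entire
gene sets held out; the joint model is trained with the remaining
associations (held-out diseases keep their EHR records, so they still get
disease vectors), and precision@K counts how many of the top-$K$ retrieved
gene tokens are in the held-out set. Two trivial comparators are included:
the global most-frequent-gene list, and genes ranked by co-occurrence of
their host diseases with the query in the records.

Ties in every ranking are broken lexicographically; skipped queries
(out-of-vocabulary held-out diseases, zero-norm vectors) are counted and
warned about, never silently dropped.

## The synthetic generator

`generate_synthetic()` plants the structure the models are meant to
exploit: each record picks one of `n_clusters` phenotype clusters and draws
its diagnoses from that cluster's diseases, each token independently
flipped to a uniformly random other-cluster disease with probability
`noise_rate`. Record lengths are $2 + \mathrm{Poisson}(\mu - 2)$ capped at
25 codes, so every record yields at least one context pair and respects the
25-diagnosis cap of discharge data; the default $\mu = 7.58$ matches the
mean diagnosis count of large inpatient databases. The first
`round(annotation_fraction x diseases_per_cluster)` diseases of each
cluster (default fraction 0.235, emulating the observed GWAS coverage of
the disease vocabulary) each receive `genes_per_disease` genes drawn
without replacement from their cluster's gene pool, so same-cluster
diseases share genes and cross-cluster pairs share none. Defaults — 10
clusters x 20 diseases, 30-gene pools, 10 genes per annotated disease,
20,000 records — are the fixed study conditions of the bundled
experiments; a Zipf (`1/rank`) within-cluster frequency profile is
available to exercise subsampling and the noise distribution.

What the generator deliberately does *not* emulate: diagnosis-rank
semantics (real lists are ordered by admission importance; generated
tokens are exchangeable — the models treat positions uniformly either
way), hierarchical code structure, record-level patient covariates, and —
most importantly — any *indirect* similarity structure. In the generator,
two diseases are similar exactly when they co-occur, which has a
consequence worth stating plainly: raw co-occurrence counting is a
sufficient statistic for cluster membership here, so co-occurrence
retrieval sits at ceiling (cluster precision@10 = 1.0) alongside the
embeddings, and a held-out disease's own genes are independent of both the
embedding ranking and the co-occurrence ranking given its cluster, making
those two gene predictors statistically equivalent on this data. Passing
the planted-cluster tests therefore demonstrates *recovery of the planted
structure*, not superiority over co-occurrence baselines — the margin the
models show on real EHR data comes from contextual similarity without
direct co-occurrence, which this generator does not manufacture.

## Numerical choices and degenerate inputs

* Gradients of a pair update are all evaluated at the pre-update point
  (outputs first, center last, from a buffered gradient), so an update is a
  clean ascent step and duplicate negatives accumulate additively.
* Sigmoids and log-sigmoids use `log1p` forms; a non-finite objective stops
  training with a "numerical divergence" error rather than poisoning the
  matrices.
* A single-token record yields no context pairs and leaves the model at
  initialization; an empty candidate pool, an unknown query, or a zero-norm
  vector raise errors naming the token.
* The comorbidity network uses the phi coefficient (Pearson correlation of
  binary incidence vectors) with $n$ = record count and keeps an edge when
  the two-sided $t$-test rejects at `alpha` (default 0.05; the level is
  configurable since the source construction does not fix it). $r = \pm 1$
  edges are kept ($t \to \infty$); diseases present in all or no records
  have undefined correlations and lose their edges with a warning. Rejected
  edges are removed, not negated; network retrieval ranks by remaining
  edge weight.
* Spectral embeddings use the symmetric normalized Laplacian per connected
  component (eigenvectors of the $d$ smallest nonzero eigenvalues);
  modularity embeddings use the top-$d$ eigenvectors of
  $B = A - kk^\top/2m$. Eigenvector signs are fixed by making the first
  nonzero coordinate positive — the constructions do not pin signs, and
  determinism requires a convention.

## Problem sizes used by the bundled experiments

The planted-cluster experiments run at the generator defaults (20,000
records, 200 diseases, 300 genes) with $D = 50$, 5 epochs — a few minutes
of CPU altogether. The property tests (gradient oracle, softmax
normalization, reduction, invariances, oracle equivalences) run on toy
instances in seconds. The numerical gradient oracle is a five-point
central-difference stencil ($O(h^4)$ truncation error, $h = 10^{-3}$), so
the comparison at relative error $10^{-5}$ tests the analytic gradients,
not the differencing scheme.

## Known limitations

* One vector per disease: a code used in several clinical contexts (e.g.
  sepsis of different origins) gets a single blended representation.
* Diagnosis rank is ignored beyond window locality; whether center or
  context roles should be weighted by list position is an open modelling
  question, and uniform treatment was adopted.
* The held-out gene protocol measures retrieval of *known* associations;
  on the synthetic data its ceiling is set by how much of a cluster's gene
  pool the training diseases cover.
* The `d2d`/`dag2d` comparison against co-occurrence baselines is only
  meaningful on data with indirect similarity structure (see the generator
  section above).
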