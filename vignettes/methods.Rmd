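---
title: "Methods: sequence encodings, neural descriptor, and Shapley-guided fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence encodings, neural descriptor, and Shapley-guided fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oripredict)
```

## The problem

Replication origins (ORIs) are the genomic loci where DNA replication
initiates. In higher eukaryotes their usage is cell-type specific, and
experimentally mapped origin sets are costly to produce, so a common task is
to learn a sequence-based classifier: given a fixed-length window (here
300 bp), predict whether it is an origin window or a flanking non-origin
window. Origin-proximal sequence is known to carry weak compositional
signals — strand-asymmetric G/C usage (GC skew) and short sequence motifs —
which is exactly the kind of signal this package's synthetic benchmark
plants and its models are built to detect.

`oripredict` implements a complete, deterministic pipeline:

1. **Data** — FASTA I/O with alphabet validation, stratified folds and
   splits, and a synthetic benchmark generator.
2. **Classical encoders** — CKSNAP, PCPseDNC/PseDNC and DCC.
3. **Neural descriptor** — a convolution / bidirectional-GRU / attention
   network trained as a classifier, then frozen as a feature extractor.
4. **Fusion and selection** — block fusion, exact TreeSHAP attributions,
   top-*k* selection.
5. **Model** — a gradient-boosted tree classifier with optional Bayesian
   hyperparameter search.
6. **Evaluation** — MCC, accuracy, sensitivity, specificity, AUC, F1 and
   precision; k-fold cross-validation; independent tests; cross-dataset
   accuracy matrices; a command-line interface.

## The synthetic benchmark

No experimental origin maps ship with the package. Instead
`generate_synthetic_dataset()` emulates the *geometry* of published origin
benchmarks at desk scale: for each simulated locus, a positive 300-bp
window and a paired negative window cut from the locus flanks, 300–600 bp
away from the positive window's edge (side chosen uniformly; 0-based
half-open coordinates internally).

Two signals are plantable in positives, both off by default weak:

- `gc_skew_shift` moves emission probability from C to G, so positives are
  G-enriched at constant G+C — a pure *skew* signal, which keeps GC content
  matched between classes and makes the benchmark harder and cleaner than a
  GC-content shift would.
- a consensus `motif` (default `ACGTACGT`) inserted at a uniform position
  with probability `motif_rate`.

What the generator deliberately does **not** emulate: chromatin context,
replication timing, repeat structure, and any correlation structure beyond
i.i.d. background emission. Results on this benchmark validate the
machinery, not biological performance.

```{r}
cfg <- synthetic_config(n_per_class = 50, gc_skew_shift = 0.1, seed = 1)
set <- generate_synthetic_dataset(cfg)
set
```

## Classical encoders

All encoders consume validated ACGT windows of one length and emit a named
`feature_block`.

**CKSNAP** (composition of *k*-spaced nucleic acid pairs). For each gap
$k \in \{0,\dots,5\}$ and each ordered pair $XY$ of bases, the frequency of
occurrences of $X$ and $Y$ separated by $k$ bases:
$f_k(XY) = N_k(XY) / (L - k - 1)$. Each 16-component sub-block sums to 1.

**PCPseDNC / PseDNC** (pseudo dinucleotide composition). A vector of
$16 + \lambda$ components built from the dinucleotide frequencies $f_m$ and
sequence-order correlation tiers
$$\theta_j = \frac{1}{L-1-j} \sum_{i=1}^{L-1-j} \Theta(d_i, d_{i+j}),
\qquad
\Theta(a, b) = \frac{1}{\mu} \sum_{u=1}^{\mu} \big(P_u(a) - P_u(b)\big)^2,$$
where $P_u$ is the $u$-th **z-standardized** physicochemical index. The
final vector is
$c_m = f_m / (\sum f + w \sum \theta)$ for $m \le 16$ and
$c_{16+j} = w\,\theta_j / (\sum f + w \sum \theta)$, so it sums to exactly 1.
Defaults: $\lambda = 2$, $w = 0.1$; PCPseDNC uses the full 38-index table
($\mu = 38$), PseDNC a 6-index subset.

**DCC** (dinucleotide cross covariance). For each ordered pair of distinct
indices $(u_1, u_2)$ and each lag $g \le$ `lag_max`:
$$\mathrm{DCC}(u_1, u_2, g) = \frac{1}{L-g-1} \sum_{i=1}^{L-g-1}
\big(P_{u_1}(d_i) - \bar P_{u_1}\big)\big(P_{u_2}(d_{i+g}) - \bar P_{u_2}\big),$$
with $\bar P_u$ the sequence-wide mean over all $L-1$ dinucleotides. The
dimension is $n_{\mathrm{idx}}(n_{\mathrm{idx}}-1) \cdot$ `lag_max`
(default $2 \cdot 1 \cdot 2 = 4$). DCC is exactly zero on homopolymers and
invariant to adding constants to raw indices — two properties the test
suite checks.

### The physicochemical index table

The encoders are defined over *a* table of dinucleotide physicochemical
indices, standardized per index to mean 0 / population SD 1 across the 16
dinucleotides (so only relative differences matter). The bundled table
(`inst/extdata/dinucleotide_properties.tsv`, 38 indices) contains:

- the SantaLucia (1998) unified nearest-neighbour thermodynamic parameters
  $\Delta G^\circ$, $\Delta H^\circ$, $\Delta S^\circ$ of each duplex step
  (*PNAS* 95:1460–1465), and
- 35 compositional descriptors that are exact by definition (GC content,
  GC/AT skew, purine/keto content, per-base counts, positional indicators,
  dinucleotide and homodimer flags).

Every value is either a published constant or a mathematical definition —
nothing is fabricated. Users with a preferred index compilation can load it
with `read_index_table()` and pass it to any encoder; the encoders
standardize raw tables on the fly.

```{r}
std <- standardize_index_table(default_index_table("full38"))
round(std$values[1:3, 1:6], 3)
```

## The neural descriptor

The network (implemented from scratch in C++ via RcppArmadillo, with
finite-difference-validated gradients and a platform-independent internal
RNG) reads the one-hot window through six parallel same-padded 1-D
convolution branches (kernels 2–12, ReLU, dropout), average-pools along the
sequence, and feeds the result to two bidirectional GRU stacks in parallel
— one 1-layer, one 2-layer. Their concatenated per-position outputs are
pooled by dot-product attention
($\mathrm{score}_t = q^\top \tanh(W_k h_t + b_k)$, softmax over $t$,
output $\sum_t \alpha_t h_t$), and a dense ReLU layer plus a 1-unit sigmoid
head produce the probability. Training is binary cross-entropy with Adam,
a seeded stratified validation split, and early stopping with best-weight
restore.

After training the network is frozen; `extract_features()` exports the
attention-pool output (or optionally the penultimate dense layer) as the
`"DL"` feature block. Two ablation switches isolate the architecture's
parts: `use_attention = FALSE` replaces attention by uniform mean pooling,
`use_gru = FALSE` lets attention pool the convolution output directly.

```{r}
arch <- arch_config(conv_filters = 4, gru_units = c(4, 6),
                    attention_dim = 6, dense_units = 8,
                    window_length = 300)
b <- train_extractor(build_extractor(arch, seed = 1), set,
                     train_config(epochs = 2, batch_size = 32, seed = 1))
dim(extract_features(b, set)$matrix)
```

## Fusion, attribution and selection

Blocks are fused column-wise in the fixed order DL, CKSNAP, PCPseDNC, DCC,
with a registry mapping column ranges to encoders. A preliminary boosted
tree model is fitted on the fused matrix and explained with **exact
TreeSHAP** values on the raw margin: per sample, a base value plus one
attribution per feature whose sum reconstructs the model margin (local
accuracy, enforced in the tests to $10^{-4}$). Features are ranked by mean
absolute attribution (ties broken by column index) and the top *k* are kept
for the final classifier. For non-tree models a seeded permutation-sampling
Shapley estimator is provided.

## Classifier and tuning

The final classifier is an xgboost gradient-boosted tree ensemble
(`binary:logistic`, single-threaded histogram method, fully seeded). The
reference formulation of this design uses an ordered-boosting engine;
that engine has no R implementation available here, so the model bundle
records `engine = "xgboost"` and `ordered_boosting = FALSE` explicitly.
Optional hyperparameter tuning is sequential model-based optimization:
a space declared with `search_param()`, a Latin-hypercube initial design,
a Gaussian-process surrogate (RBF kernel on the unit cube) and
expected-improvement acquisition, maximizing a cross-validated MCC
objective computed on training data only.

## Evaluation

`compute_metrics()` reports MCC, accuracy, sensitivity, specificity, AUC
(Mann–Whitney rank statistic with midrank ties), F1 and precision, with
explicit zero/NA conventions for degenerate confusion tables.
`cross_validate()` refits the *entire* pipeline — extractor, encoders,
selection, classifier — inside each fold, so no test information leaks into
selection or tuning. `cross_cell_matrix()` trains one model per tagged
dataset and scores all pairwise train/test accuracies.

```{r}
cv <- cross_validate(
  pipeline_config(blocks = "CKSNAP", boost = boost_params(n_trees = 60),
                  seed = 1),
  set, split_folds(set, n_folds = 5, seed = 1))
round(cv$mean, 3)
```

## Numerical and reproducibility choices

- All stochastic steps are seeded; R-side randomness runs under an
  RNG-state-restoring `with_seed()`, and the C++ network uses its own
  mt19937-64 + Box–Muller generator, so results are identical across
  platforms and independent of the caller's RNG state.
- Index standardization uses the population SD over the 16 dinucleotides
  and refuses constant indices.
- The problem sizes used throughout the documentation and tests
  (500 windows per class, 300 bp, compact extractor settings) are this
  package's own desk-scale choices: large enough for stable statistics,
  small enough that the full test suite and the acceptance script run in
  minutes on one core.

## Limitations

- The benchmark is synthetic; numbers obtained on it say nothing about
  performance on experimental origin maps.
- The boosted-tree engine is conventional gradient boosting, not ordered
  boosting.
- The bundled index table is a documented, user-replaceable stand-in for
  the larger curated compilations used in parts of the literature.
- The network is CPU-only and intentionally compact; it is a feature
  descriptor, not a competitive deep architecture.
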