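---
title: "Physicochemical k-mer profiles: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical k-mer profiles: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmer)
```

## The encoding

Alignment-free sequence comparison usually starts from the k-mer spectrum:
a sequence of length $l_S$ is represented by the counts of all $4^k$
nucleotide words of length $k$, equivalently by the cell counts of a
frequency chaos-game representation (FCGR). The spectrum grows
exponentially in $k$, which is what limits k-mer methods in practice.

This package implements a grouped alternative built on the physicochemical
structure of the nucleotide alphabet. Each of three chemically meaningful
partitions of $\{A, C, G, T\}$ re-writes the sequence over a two-letter
alphabet:

| scheme | low group $\to$ symbol | high group $\to$ symbol | chemistry |
|---|---|---|---|
| `purine_pyrimidine` | A, G $\to$ R | C, T $\to$ Y | ring count |
| `amino_keto`        | A, C $\to$ M | G, T $\to$ K | major-groove group |
| `weak_strong`       | C, G $\to$ S | A, T $\to$ W | 3 vs 2 H-bonds |

Each two-letter string is then profiled by a one-dimensional chaos game on
cells $1 \dots 2^k$. With the walk at cell $\mathrm{ind}_{j-1}$ and the
$j$-th symbol carrying endpoint $\alpha \in \{0, 2^k\}$ (low and high
symbol respectively), the update is

$$\mathrm{ind}_j = \left\lceil \frac{\mathrm{ind}_{j-1} + \alpha}{2} \right\rceil,
\qquad \mathrm{ind}_0 = 2^k / 2,$$

and the landed cell is incremented. In 0-based coordinates
$x = \mathrm{ind} - 1$ the update is the shift
$x' = \lfloor x/2 \rfloor + b \cdot 2^{k-1}$ with $b \in \{0, 1\}$, so
after $k$ symbols the cell encodes exactly the last $k$ binary symbols,
with the most recent symbol as the most significant bit of $x$. A
sequence therefore maps to three $2^k$ count vectors —
$3 \cdot 2^k$ features in place of $4^k$, a reduction by the factor
$4^k / (3 \cdot 2^k)$ ($\approx 1365$ at $k = 12$).

Two facts make the grouped profile trustworthy, and both are enforced by
the test suite rather than assumed:

* **Oracle equivalence.** In `kmer_only` mode every cell equals the count
  of one binary k-mer of the re-alphabeted string. The suite checks the
  walk bit-exactly against `brute_force_binary_kmer_counts()`, an
  independent substring-enumeration counter, over randomized panels for
  $k = 1 \dots 8$.
* **Group collapse.** The $4^k$ classical k-mers fall, per scheme, into
  $2^k$ classes of $2^k$ members (all words with the same per-position
  physicochemical image), and summing FCGR counts over each class
  reproduces the PC-mer vector: `group_collapse(encode_fcgr(s, k)) ==
  encode_pcmer(s, k)`. This identity is checked bit-exactly for
  $k = 1 \dots 6$.

### Numerical and boundary choices

* **High endpoint $2^k$.** The recurrence only enumerates all $2^k$ cells
  bijectively when the endpoints are $0$ and $2^k$; the midpoint start
  $2^k/2$ confirms the walk lives on the interval $[0, 2^k]$. Any smaller
  high endpoint collapses the walk onto a sub-interval and destroys the
  k-mer interpretation, so $\{0, 2^k\}$ is fixed, not tunable.
* **Counting modes.** `all_positions` increments from the first symbol
  onward; the first $k-1$ increments land in partial-prefix cells. It is
  the default for feature extraction (profiles then sum to $l_S$).
  `kmer_only` counts only complete windows (sums to $l_S - k + 1$) and is
  the mode under which the oracle and collapse identities hold exactly.
  Classification results are insensitive to the choice — the modes differ
  in at most $k - 1$ counts per scheme — but verification demands the
  exact semantics, so both are exposed.
* **Ambiguity codes.** Residues outside A/C/G/T (after upper-casing and
  U$\to$T) break the walk: it resets to the midpoint and the window
  counter restarts, the standard behaviour of k-mer counters that split
  sequences at ambiguous bases. Skipping such residues without a reset
  would silently corrupt k-mer identities and is deliberately not offered.
* **Cell indexing** is 1-based ($1 \dots 2^k$), matching the recurrence,
  and the serialized column order is
  `purine_pyrimidine_1..2^k, amino_keto_*, weak_strong_*`.
* **Raw counts by default.** Profiles are integer counts;
  `normalize_profile()` converts to per-position frequencies when
  sequences differ materially in length. Counts are the default because
  downstream classifiers received counts in the workflows this package
  targets and read sets there are near-uniform in length.
* **k limits**: $1 \le k \le 24$ for PC-mer ($3 \cdot 2^{24}$ doubles is
  still desktop-sized) and $k \le 12$ for the FCGR baseline ($4^{12}$
  cells). The CLI default is $k = 12$, the upper end of the useful range
  for 16S-scale inputs, where classification accuracy is typically
  highest.

## Distance-based comparison

`pairwise_distances()` uses the Manhattan (L1) distance between
concatenated profiles as the dissimilarity score. Two evaluation numbers
are defined on a labeled distance matrix:

* **Retrieval AUC** (`retrieval_auc()`): each sequence in turn is a query;
  all others are ranked by ascending distance; same-label sequences are
  positives; the ROC AUC of that ranking is computed with midrank tie
  handling and averaged (unweighted) over queries. This leave-one-out
  construction is the standard label-free score for a distance matrix, is
  invariant under any strictly monotone transform of the distances, and
  equals 0.5 exactly when all distances tie. Queries from singleton
  classes have no positives and are excluded with a warning.
* **Matrix correlation** (`matrix_correlation()`): the Pearson correlation
  over strict upper-triangle entries of two matrices with identical id
  order. No permutation p-value is attached — the coefficient itself is
  the quantity of interest. A zero-variance triangle makes the
  coefficient undefined; it is returned as `NA` with a warning rather
  than silently as 0.

Alignment-based reference dissimilarities (e.g. Smith–Waterman) are not
implemented; when a reference matrix is supplied it is read from a TSV.
For self-contained validation, the synthetic divergence series provides a
known ground truth: substitution rates play the role of true divergence,
and the suite requires the Spearman correlation between rate and mean
distance from the ancestor to exceed 0.9.

## Classification harness

`cross_validate()` runs stratified k-fold cross-validation (default 10
folds, lowered with a warning when the smallest class is smaller) with
the fold assignment and every stochastic fit driven by one integer seed.
Eight basic classifier configurations are provided (see
`?classifier_spec`); fixed hyperparameters are: logistic regression with
L2 penalty, one-vs-rest, C = 1, tolerance $10^{-4}$; decision tree with
Gini impurity; Gaussian naive Bayes; LDA; an MLP with one 100-neuron
hidden layer, weight decay $10^{-4}$, at most 200 passes; linear SVC with
cost 1; nearest centroid to the class mean (Euclidean) and to the
per-feature class median (Manhattan). Everything else stays at the
backing R library's defaults.

Fidelity notes on the R backends, chosen deliberately:

* One-vs-rest L2 logistic regression is fit as one ridge `glmnet`
  binomial model per class at $\lambda = 1/(nC)$, the penalty that makes
  the glmnet objective coincide with the C-parameterized regularized
  log-loss.
* `nnet`'s single-hidden-layer network uses logistic activations and
  BFGS; ReLU activations and Adam are not available in any installed R
  MLP and the difference is immaterial for a 100-unit single layer on
  count features.
* `e1071::svm` optimizes hinge loss (libsvm) rather than squared hinge.
* LDA drops features with (numerically) zero pooled within-class
  variance before fitting, and the structural collinearity warning — the
  three blocks of a profile each sum to the same total — is muffled.

Metrics: accuracy, precision, recall and F1 are computed per fold from
the fold's confusion matrix; macro averages are primary (class sets above
the genus level are typically unbalanced, and macro averaging makes
minority-class failure visible), weighted averages are recorded
alongside. Per-class precision with an empty prediction column is defined
as 0. The report carries both the arithmetic mean of fold metrics and the
pooled accuracy from the summed confusion matrix; the two coincide when
fold sizes are equal and the suite requires pooled accuracy to equal the
confusion-matrix accuracy to $10^{-12}$. Ties in classifier scores are
broken toward the first class level, fixed, so reruns are bit-identical
for deterministic classifiers.

## What the synthetic generator emulates — and what it does not

`generate_class_dataset()` draws each class from an order-1 Markov chain
over A/C/G/T. This is the minimal model that gives classes distinct k-mer
spectra for every $k \ge 2$, so it exercises exactly the signal the
encoding is meant to capture. `random_class_models()` mixes class
matrices with a shared matrix (`separation` in $[0,1]$), giving graded
difficulty from indistinguishable to independent;
`mutate_sequence()`/`make_divergence_series()` add point substitutions
(uniform over the three alternatives) and optional indels
(deletion and insertion each at half the indel rate), with indels off by
default so window-count conservation stays exact.

Reference panel sizes used by the validation suite, chosen to estimate
each property stably at desktop scale: 200 random sequences of length
50–500 for the encoder identities ($k = 1..8$; 100 sequences and
$k \le 6$ for the collapse identity, which costs $4^k$ per check); a
5-class Markov panel of 100 sequences per class, length 500, independent
transition matrices, for classification recovery (logistic regression,
10-fold CV, $k \in \{3, 8\}$); a divergence series over rates
0.01–0.30 with 20 replicates per rate from a 1000-base ancestor; a
2-class panel of 25 sequences per class, length 400, for the
PC-mer-vs-FCGR retrieval comparison; and a 3-class panel of 30 per class
for null calibration (label permutations must give chance-level accuracy
and AUC).

What passing these tests does **not** show about real data: Markov
sequences have no phylogenetic correlation structure, no conserved and
variable regions, no sequencing-platform error profile, and no class
imbalance unless requested. Accuracy on the synthetic panels says the
pipeline recovers compositional signal that is genuinely present; it does
not predict accuracy on any particular amplicon or shotgun dataset, where
class separation is a property of the organisms, the marker gene and the
read length.

## Known limitations

* Reverse complements are not canonicalized: a sequence and its reverse
  complement generally produce different profiles. (Under
  `purine_pyrimidine` and `amino_keto` the reverse complement maps to the
  reversed complement string; no folding is attempted.)
* The FCGR baseline is capped at $k = 12$ and `group_collapse()` builds
  its $4^k$-to-$2^k$ index map in memory, so the collapse identity is
  practical up to $k \approx 10$.
* The MLP configuration is faithful in architecture and penalty but not
  in optimizer (see above); for that reason the suite treats MLP results
  with tolerance bands, never exact floats.
* `retrieval_auc()` is quadratic in the number of sequences; matrices
  beyond a few thousand sequences are better sampled.
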