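---
title: "Assessing machine-learning readiness of tabular data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing machine-learning readiness of tabular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabready)
```

## The problem

Most applied machine-learning effort goes into deciding which parts of a raw
table are worth modelling. Clinical and cohort exports in particular arrive
with redundant variables, missing cells, corrupted measurements and
ambiguous diagnoses, and the usual response — hand-curated inclusion rules —
is slow and hard to justify. `tabready` automates one concrete version of
this task for a labeled table `D` of `N` rows and `M` columns (one column
being a categorical class label): find a sub-table `T*`, formed by deleting
some rows and feature columns, that maximizes a *dataset-specific* measure
of readiness for classification and clustering.

## The model

### Five quality metrics

Every (sub-)table is scored on five metrics `f_1..f_5`, each normalized to
`[0, 1]` with 1 best, in the fixed order Pearson, Spearman, Missing,
Outliers, ClassOverlap:

* **Pearson redundancy** `1 - mean(|r|)` over all unordered feature pairs.
  Pairwise-complete observations are used, so correlation never depends on
  imputation; pairs with an undefined coefficient (constant column, fewer
  than two complete pairs) contribute 0, because a constant column carries
  no redundancy signal. The *absolute* coefficient is averaged: negative
  correlation is still redundancy, and the aggregate must stay in `[0, 1]`.
* **Spearman redundancy**, identically aggregated on rank correlations with
  mid-rank tie handling. On tie-free data this equals the textbook
  `1 - 6 Σ d_i² / (n(n²-1))` formula; mid-ranks extend it to the heavily
  tied data clinical tables actually contain.
* **Completeness** `1 - MV`, the complement of the missing-cell fraction
  over feature cells.
* **Outlier cleanliness.** A cell is an outlier when `|x - median(X)| / MAD
  > 3` within its column (raw ratio, no 1.4826 consistency constant, and a
  column with `MAD = 0` flags nothing). The score is `1 -` the fraction of
  *rows containing at least one flagged cell*. The row-level aggregation is
  a declared design choice: a per-cell or per-column reading of "`1 - MAD`"
  is dimensionally inconsistent, and no integer row count reproduces every
  published value, so this score should be compared across sub-tables of
  one dataset rather than across publications.
* **Class non-overlap** `1 - R`. A sample is overlapped when strictly more
  than `θ` of its `k` nearest neighbours (default `k = 7`, `θ = 3`: "at
  least four of seven") belong to a foreign class. Distances are Euclidean
  on unstandardized, median-imputed features; the self is excluded and
  distance ties are broken by ascending row index so the statistic is
  exactly reproducible. `R` is the overlapped fraction, computed by an
  `O(N²)` scan.

### ML accuracy of a sub-table

The readiness weights are learned against what the data are *for*: a
sub-table's combined accuracy is the equal-weight mean of

* mean stratified 10-fold cross-validated classification accuracy, averaged
  over a 20-tree random-forest classifier and a linear hinge-loss SGD
  classifier, and
* the mean silhouette coefficient, averaged over k-means (k-means++
  seeding, Lloyd iterations) and Ward agglomerative clustering, each cut at
  as many clusters as there are label classes, with each algorithm's mean
  silhouette clamped from `[-1, 0]` to 0 before averaging.

Folds are stratified (unstratified folds can lose a rare class entirely in
a small sub-table) and shrink to the smallest class count when necessary,
with a floor of two. Missing cells are median-imputed per column before any
learner runs; features are standardized internally for the SGD classifier
only, because gradient-descent linear models diverge on raw clinical
scales, while forests, clusterings and silhouettes see the raw geometry.

Because no random-forest implementation ships with this package's target
environment, the forest classifier, the forest regressor and its
impurity-decrease importances are implemented natively (in C++): CART trees
grown to purity, Gini / variance criteria, `floor(sqrt(F))` candidate
features per split for classification and all features for regression,
matching the defaults of the ecosystem the method was published in. All
stochastic routines draw from R's RNG stream, so a single `set.seed()`
governs the entire pipeline.

### Weight learning and the readiness space

Each run samples `d` sub-tables: the number of rows to drop is uniform on
`{0..⌊RER·N⌋}` and columns on `{0..min(F-2, ⌊CER·F⌋)}` (defaults
`RER = 0.2`, `CER = 0.5`), the dropped sets are uniform without
replacement, and a draw is rejected unless at least two classes with at
least two members each survive. The `d × 5` matrix of quality scores plus
the combined accuracies form the readiness space `D′`; a 20-tree forest
regression of accuracy on the five scores yields, via normalized impurity
importances, that run's weight vector `W_r` (a constant target falls back
to the uniform vector). The per-drop-count-uniform scheme is a declared
choice — the alternative per-element coin-flip scheme concentrates the
dropped fraction and explores the extremes less.

After `R` runs (run `r` seeded with `seed + r`, so any degree of
parallelism yields identical results), `W* = mean(W_1..W_R)` renormalized
to unit sum, every stored record is scored with the total quality
`f̃ = Σ w_i f_i`, and the best record per run and overall are selected (ties
broken by higher combined accuracy, then lower run id, then lower record
id). `f̃` is computed only under `W*`, after weight learning — per-run
weights are retained for transparency but never used for selection. Weights
are fit per run and averaged rather than pooled across runs, mirroring the
random-restart framing in which each run is an independent local search.

## The synthetic world

`generate_dataset()` produces the only data the tests need: Gaussian class
blobs whose means sit `class_separation` within-class standard deviations
apart (class `c` occupies axis `c`, so all pairwise mean distances are
exactly the stated separation), exact duplicate features, pure-noise
features, MCAR missingness restricted to a chosen number of columns,
MAD-calibrated outlier cells (shifted away from the column median by
`magnitude · (3·MAD + ε)`, so any magnitude above 1 must trip the detector)
and uniformly re-assigned labels for a fraction of rows. Mislabeling
changes labels but not geometry, so it moves the class-overlap dial without
touching the clustering structure.

The canonical benchmark world, `planted_junk_spec()`, is a 500 × 30 table:
15 informative features at separation 3 across 3 classes, 5 duplicates, 10
noise columns, 50% missingness on 6 columns, 2% outlier cells at magnitude
2, and 10% mislabeled rows. These settings were chosen once as a plausible
mid-quality clinical table — moderate class overlap, roughly half the
columns junk — and are not tuned against any test outcome. What a green
end-to-end test establishes is that the search removes *planted* junk in a
world matching its assumptions (numeric features, MCAR missingness,
label-preserving geometry); it says nothing about informative missingness,
batch effects, or categorical predictors, which the generator does not
emulate.

## Numerical choices and degenerate inputs

* Columns are retained as numeric when ≥ 99% of their non-missing entries
  parse as numbers (stray footnote characters become missing cells); the
  tokens `""`, `"NA"`, `"NaN"`, `"null"` (case-insensitive) parse as
  missing. Rows with a missing label are dropped with a warning.
* A numeric-but-unwanted column (an identifier, an age used elsewhere) can
  be excluded by name via the `exclude` list — the generalization of the
  manual exclusions the original analyses applied.
* An all-missing column median-imputes to 0; a clustering that returns a
  single non-empty cluster, or fails outright, contributes 0 to the
  clustering score.
* `total_quality()` accepts weight vectors whose sum differs from 1 by up
  to 1e-3, so published vectors rounded to four decimals remain usable.
  On that note: dot products of *published, 4-decimal-rounded* scores and
  weights carry up to ~2e-4 of input rounding error, and indeed each of the
  three published worked examples lands one unit of the fourth decimal away
  from the published total computed from unrounded internals. The
  acceptance suite asserts `|diff| ≤ 1e-4`; the ADNI example misses that
  band by 1.1e-5 and its expectation is deliberately left failing rather
  than widening the band after measurement.
* Reports serialize floats at six decimals, data at full `%.17g` precision
  (so a written table reloads bit-identically), and all indices 0-based.

## Known limitations

* The search is a random restart over uniform deletions; it has no notion
  of which columns hurt, so its sample efficiency degrades with table
  width. Smarter proposals (greedy, Bayesian) are out of scope.
* The outlier score's row-level aggregation saturates for wide tables —
  with many columns almost every row contains some flagged cell, pushing
  the score toward 0 and its learned weight toward 0 correspondingly.
* Classification accuracy of the bundled WDBC table under this package's
  two classifiers is ≈ 0.96, far above the published 0.48 for the same
  data; the published figure is not reproducible from the stated method and
  is treated as out of scope, exactly like the outlier score's printed
  value (0.0875 corresponds to no integer count of 569 rows).
* With `d` sub-tables per run the per-run cost is dominated by `d` forest
  cross-validations; the package evaluates roughly 6-10 records per second
  per core at the 500 × 30 scale.
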