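#' ML-based accuracy of a sub-table
#'
#' A sub-table's usefulness for machine learning is scored two ways and the
#' two are averaged with equal weight:
#'
#' * **Classification**: mean stratified cross-validated accuracy, averaged
#'   over a random-forest classifier (`n_estimators` trees) and a linear
#'   hinge-loss classifier trained by stochastic gradient descent. Folds
#'   default to `cv_folds` but are reduced to the smallest class count when
#'   a class is rarer than the fold count (floor 2).
#' * **Clustering**: mean silhouette coefficient, computed for k-means
#'   (k-means++ initialization, Lloyd iterations) and agglomerative
#'   clustering (Ward linkage, Euclidean), each cut at as many clusters as
#'   there are label classes; each algorithm's mean silhouette is clamped
#'   from `[-1, 0]` to 0 before the two are averaged.
#'
#' Missing cells are median-imputed per column (sub-table-local medians)
#' before any learner runs. Features are standardized internally for the
#' SGD classifier only; forests, clusterings and silhouettes see the raw
#' (imputed) scales.
#'
#' All routines consume R's RNG stream: wrap calls in `set.seed()` (or pass
#' `seed`) for bit-identical results.
#'
#' @param x a [master_table()] (or materialized sub-table).
#' @param config a [search_config()].
#' @param seed optional integer; when given, the RNG is seeded before
#'   evaluation so the score is a pure function of `(x, config, seed)`.
#' @return a score in `[0, 1]`.
#' @name ml_eval
NULL

stratified_folds <- function(labels, k) {
  k <- max(2L, min(k, min(table(labels))))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

standardize_cols <- function(train, test) {
  mu <- colMeans(train)
  sdv <- matrixStats::colSds(train)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(train, 2L, mu, "-"), 2L, sdv, "/"),
       test = sweep(sweep(test, 2L, mu, "-"), 2L, sdv, "/"))
}

#' @rdname ml_eval
#' @export
classification_accuracy <- function(x, config = search_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- droplevels(x$labels)
  if (nlevels(labels) < 2L) stop("classification needs at least 2 classes")
  m <- impute_median(x$features)
  y <- as.integer(labels) - 1L
  nclass <- nlevels(labels)
  fold <- stratified_folds(labels, config$cv_folds)
  nfold <- max(fold)
  mtry <- max(1L, floor(sqrt(ncol(m))))
  rf_acc <- sgd_acc <- numeric(nfold)
  for (f in seq_len(nfold)) {
    te <- fold == f
    rf_pred <- cpp_rf_classify(m[!te, , drop = FALSE], y[!te], nclass,
                               m[te, , drop = FALSE],
                               config$n_estimators, mtry)
    rf_acc[f] <- mean(rf_pred == y[te])
    std <- standardize_cols(m[!te, , drop = FALSE], m[te, , drop = FALSE])
    w <- cpp_sgd_hinge_fit(std$train, y[!te], nclass,
                           epochs = 10L, alpha = 1e-4)
    sgd_acc[f] <- mean(cpp_linear_predict(std$test, w) == y[te])
  }
  (mean(rf_acc) + mean(sgd_acc)) / 2
}

# k-means++ seeding: first center uniform, then data points with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(m, 2L, m[centers[1L], ], "-")^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[i + 1L] <- sample.int(n, 1L)
    } else {
      centers[i + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(m, 2L, m[centers[i + 1L], ], "-")^2))
  }
  m[centers, , drop = FALSE]
}

mean_silhouette <- function(m, cl) {
  cl <- as.integer(factor(cl))
  if (length(unique(cl)) < 2L) return(0)
  mean(cpp_silhouette_samples(m, cl - 1L, max(cl)))
}

#' @rdname ml_eval
#' @export
clustering_accuracy <- function(x, config = search_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- droplevels(x$labels)
  k <- nlevels(labels)
  if (k < 2L) stop("clustering accuracy needs at least 2 label classes")
  m <- impute_median(x$features)
  if (nrow(m) < k + 1L) stop("too few samples for clustering")

  km_sil <- tryCatch({
    centers <- kmeanspp_centers(m, k)
    fit <- suppressWarnings(stats::kmeans(m, centers = centers,
                                          iter.max = 100L,
                                          algorithm = "Lloyd"))
    mean_silhouette(m, fit$cluster)
  }, error = function(e) 0)

  ag_sil <- tryCatch({
    hc <- stats::hclust(stats::dist(m), method = "ward.D2")
    mean_silhouette(m, stats::cutree(hc, k = k))
  }, error = function(e) 0)

  (max(0, km_sil) + max(0, ag_sil)) / 2
}

#' Combined accuracy
#'
#' Equal-weight arithmetic mean of the classification and clustering
#' scores; this combined value is the regression target when metric
#' weights are learned.
#'
#' @param classification classification score in `[0, 1]`.
#' @param clustering clustering score in `[0, 1]`.
#' @return their mean.
#' @export
combined_accuracy <- function(classification, clustering) {
  stopifnot(classification >= 0, classification <= 1,
            clustering >= 0, clustering <= 1)
  (classification + clustering) / 2
}

# the full AccuracyRecord for one sub-table
evaluate_subtable <- function(x, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  clf <- classification_accuracy(x, config)
  clu <- clustering_accuracy(x, config)
  list(classification = clf, clustering = clu,
       combined = combined_accuracy(clf, clu))
}
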