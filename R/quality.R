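#' Quality metrics
#'
#' Five data-quality scores, each normalized to `[0, 1]` with 1 meaning
#' best, computed on the feature matrix of a (sub-)table:
#'
#' * `pearson_quality`: `1 - mean(|r|)` over all unordered feature pairs,
#'   `r` the Pearson coefficient on pairwise-complete observations. High
#'   pairwise correlation means redundant features, hence a low score.
#' * `spearman_quality`: same with the Spearman rank coefficient
#'   (mid-ranks for ties), sensitive to monotone non-linear redundancy.
#' * `missing_quality`: `1 -` fraction of missing feature cells.
#' * `outlier_quality`: `1 -` fraction of rows containing at least one
#'   cell flagged by the MAD rule `|x - median| / MAD > 3` (columns with
#'   `MAD = 0` flag nothing).
#' * `class_overlap_quality`: `1 - R`, where R is the fraction of samples
#'   with strictly more than `theta` foreign-class labels among their `k`
#'   nearest neighbours (Euclidean distance on median-imputed,
#'   unstandardized features, self excluded, ties broken by row index).
#'
#' Pairs whose correlation is undefined (constant column, fewer than two
#' complete observation pairs) contribute 0 to the correlation means: a
#' constant column carries no redundancy signal.
#'
#' @param x a [master_table()] or a numeric feature matrix.
#' @return a score in `[0, 1]` for the correlation and missingness metrics;
#'   `outlier_quality` and `class_overlap_quality` return a list with
#'   `$score` plus a diagnostic report (see Details).
#' @name quality_metrics
NULL

feature_matrix <- function(x) {
  if (inherits(x, "master_table")) x$features else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

mean_abs_offdiag <- function(cmat) {
  vals <- cmat[upper.tri(cmat)]
  vals[!is.finite(vals)] <- 0
  mean(abs(vals))
}

#' @rdname quality_metrics
#' @export
pearson_quality <- function(x) {
  m <- feature_matrix(x)
  if (ncol(m) < 2L) stop("correlation quality needs at least 2 feature columns")
  cmat <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs",
                                      method = "pearson"))
  1 - mean_abs_offdiag(cmat)
}

#' @rdname quality_metrics
#' @export
spearman_quality <- function(x) {
  m <- feature_matrix(x)
  p <- ncol(m)
  if (p < 2L) stop("correlation quality needs at least 2 feature columns")
  has_na <- colSums(is.na(m)) > 0L
  npair <- p * (p - 1) / 2
  total <- 0
  # complete columns: rank once, correlate ranks in one shot
  cc_idx <- which(!has_na)
  if (length(cc_idx) >= 2L) {
    r <- apply(m[, cc_idx, drop = FALSE], 2L, rank)
    cmat <- suppressWarnings(stats::cor(r))
    vals <- cmat[upper.tri(cmat)]
    vals[!is.finite(vals)] <- 0
    total <- total + sum(abs(vals))
  }
  # pairs touching a column with missing cells: pairwise-complete re-ranking
  # (ranks must be recomputed on each pair's complete cases)
  na_idx <- which(has_na)
  for (j in na_idx) {
    partners <- c(cc_idx, na_idx[na_idx > j])
    obs_j <- !is.na(m[, j])
    for (k in partners) {
      both <- obs_j & !is.na(m[, k])
      if (sum(both) < 2L) next
      rho <- suppressWarnings(stats::cor(rank(m[both, j]), rank(m[both, k])))
      if (is.finite(rho)) total <- total + abs(rho)
    }
  }
  1 - total / npair
}

#' @rdname quality_metrics
#' @export
missing_quality <- function(x) {
  m <- feature_matrix(x)
  if (length(m) == 0L) stop("empty feature matrix")
  1 - mean(is.na(m))
}

#' @rdname quality_metrics
#' @details `outlier_quality` returns `$score`, per-column `$medians` and
#'   `$mads`, the logical `$flags` matrix (FALSE at missing cells), and
#'   `$flagged_row_count`.
#' @export
outlier_quality <- function(x) {
  m <- feature_matrix(x)
  if (all(is.na(m))) stop("all feature cells are missing")
  med <- matrixStats::colMedians(m, na.rm = TRUE)
  dev <- abs(sweep(m, 2L, med, "-"))
  mad <- matrixStats::colMedians(dev, na.rm = TRUE)
  # MAD = 0 columns flag nothing (raw ratio, no 1.4826 consistency constant)
  denom <- ifelse(mad > 0, mad, Inf)
  flags <- sweep(dev, 2L, denom, "/") > 3
  flags[is.na(flags)] <- FALSE
  flagged_rows <- rowSums(flags) > 0L
  structure(
    list(score = 1 - mean(flagged_rows),
         medians = med, mads = mad, flags = flags,
         flagged_row_count = sum(flagged_rows)),
    class = "outlier_report"
  )
}

# per-column median imputation; columns with no observed value become 0
impute_median <- function(m) {
  if (!anyNA(m)) return(m)
  med <- matrixStats::colMedians(m, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in which(colSums(is.na(m)) > 0L)) {
    m[is.na(m[, j]), j] <- med[j]
  }
  m
}

#' @rdname quality_metrics
#' @details `class_overlap_quality` returns `$score = 1 - R`, `$r_value`,
#'   the per-sample `$foreign_counts`, and the logical `$overlapped` mask.
#' @param labels class labels (required when `x` is a bare matrix).
#' @param knn_k neighbour count (default 7).
#' @param knn_theta overlap threshold (default 3): overlapped iff
#'   `foreign_count > knn_theta`.
#' @export
class_overlap_quality <- function(x, labels = NULL, knn_k = 7L, knn_theta = 3) {
  m <- feature_matrix(x)
  if (is.null(labels) && inherits(x, "master_table")) labels <- x$labels
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("class overlap needs at least 2 classes")
  if (nrow(m) <= knn_k) stop("class overlap needs more samples than knn_k")
  m <- impute_median(m)
  counts <- cpp_knn_foreign_counts(m, as.integer(labels) - 1L, as.integer(knn_k))
  overlapped <- counts > knn_theta
  r <- mean(overlapped)
  structure(
    list(score = 1 - r, r_value = r,
         foreign_counts = counts, overlapped = overlapped),
    class = "overlap_report"
  )
}

#' Compute the five-score quality vector
#'
#' Fixed order: Pearson, Spearman, Missing, Outliers, ClassOverlap. Every
#' component lies in `[0, 1]` with 1 meaning best.
#'
#' @param x a [master_table()] (or sub-table).
#' @param config a [search_config()]; supplies `knn_k` and `knn_theta`.
#' @return named numeric vector of length 5.
#' @export
compute_quality_vector <- function(x, config = search_config()) {
  c(pc = pearson_quality(x),
    spearman = spearman_quality(x),
    missing = missing_quality(x),
    outlier = outlier_quality(x)$score,
    overlap = class_overlap_quality(x, knn_k = config$knn_k,
                                    knn_theta = config$knn_theta)$score)
}

quality_metric_names <- function() c("pc", "spearman", "missing", "outlier", "overlap")
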