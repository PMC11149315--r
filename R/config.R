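#' Search configuration
#'
#' Bundles every tunable of the readiness pipeline. Defaults follow the
#' framework's published settings: at most 20% of rows and 50% of feature
#' columns may be dropped when sampling a sub-table (`RER = 0.2`,
#' `CER = 0.5`), class overlap uses `k = 7` nearest neighbours with
#' threshold `theta = 3` ("at least four of seven foreign"), classification
#' uses 10-fold cross-validation, and both the forest classifier and the
#' forest regressor grow 20 trees.
#'
#' @param d sub-tables sampled per run (positive integer).
#' @param R number of random-restart runs.
#' @param RER row exclusion ratio in `[0, 1)`.
#' @param CER column exclusion ratio in `[0, 1)`.
#' @param knn_k neighbour count for the class-overlap R value.
#' @param knn_theta overlap threshold, in `[0, knn_k / 2]`; a sample is
#'   overlapped when strictly more than `knn_theta` of its `knn_k`
#'   neighbours carry a foreign label.
#' @param cv_folds cross-validation folds (>= 2).
#' @param n_estimators trees for the forest classifier and regressor.
#' @param seed base random seed; run `r` uses `seed + r`.
#' @param jobs maximum concurrent runs (forked workers; results are
#'   schedule-invariant because seeding is per run).
#' @param standardize z-score the master's feature columns before any
#'   analysis (default `FALSE`; distances are taken on raw scales).
#' @param exclude column names dropped at load time even if numeric.
#' @return an object of class `search_config`.
#' @export
search_config <- function(d = 100L, R = 1L, RER = 0.2, CER = 0.5,
                          knn_k = 7L, knn_theta = 3L, cv_folds = 10L,
                          n_estimators = 20L, seed = 1L, jobs = 1L,
                          standardize = FALSE, exclude = character()) {
  cfg <- list(d = as.integer(d), R = as.integer(R), RER = RER, CER = CER,
              knn_k = as.integer(knn_k), knn_theta = as.numeric(knn_theta),
              cv_folds = as.integer(cv_folds),
              n_estimators = as.integer(n_estimators),
              seed = as.integer(seed), jobs = as.integer(jobs),
              standardize = isTRUE(standardize),
              exclude = as.character(exclude))
  validate_config(cfg)
  structure(cfg, class = "search_config")
}

validate_config <- function(cfg) {
  if (cfg$d < 1L) stop("d must be a positive integer")
  if (cfg$R < 1L) stop("R must be a positive integer")
  if (!is.numeric(cfg$RER) || cfg$RER < 0 || cfg$RER >= 1)
    stop("RER must lie in [0, 1)")
  if (!is.numeric(cfg$CER) || cfg$CER < 0 || cfg$CER >= 1)
    stop("CER must lie in [0, 1)")
  if (cfg$knn_k < 1L) stop("knn_k must be positive")
  if (cfg$knn_theta < 0 || cfg$knn_theta > cfg$knn_k / 2)
    stop("knn_theta must lie in [0, knn_k / 2]")
  if (cfg$cv_folds < 2L) stop("cv_folds must be at least 2")
  if (cfg$n_estimators < 1L) stop("n_estimators must be positive")
  if (cfg$jobs < 1L) stop("jobs must be positive")
  invisible(cfg)
}

#' Read / write a search configuration as JSON
#'
#' The JSON file mirrors the [search_config()] field names; absent fields
#' fall back to the defaults.
#'
#' @param path JSON file path.
#' @return [read_config()] returns a `search_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(search_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(search_config, vals)
}

#' @rdname read_config
#' @param cfg a `search_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "search_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.search_config <- function(x, ...) {
  cat(sprintf(
    "<search_config> d=%d R=%d RER=%.2f CER=%.2f k=%d theta=%g folds=%d trees=%d seed=%d jobs=%d\n",
    x$d, x$R, x$RER, x$CER, x$knn_k, x$knn_theta, x$cv_folds,
    x$n_estimators, x$seed, x$jobs))
  invisible(x)
}
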