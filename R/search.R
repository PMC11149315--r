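#' Sample a random sub-table index
#'
#' Draws the number of rows to drop uniformly from `{0, ..., floor(RER*N)}`
#' and the number of feature columns to drop uniformly from
#' `{0, ..., min(F-2, floor(CER*F))}`, then picks the dropped sets uniformly
#' without replacement. A draw is rejected (and retried, at most
#' `max_attempts` times) when the induced label column has fewer than two
#' classes or any class with fewer than two members — cross-validation and
#' silhouettes are undefined below that floor.
#'
#' Indices are 0-based, strictly increasing, into the master's rows and
#' feature columns; the label column is implicitly always retained.
#'
#' @param master a [master_table()].
#' @param config a [search_config()].
#' @param max_attempts resampling budget before giving up.
#' @return an object of class `subtable_index` with `$rows` and `$cols`.
#' @export
sample_subtable <- function(master, config = search_config(),
                            max_attempts = 100L) {
  n <- nrow(master$features)
  f <- ncol(master$features)
  max_row_drop <- floor(config$RER * n)
  max_col_drop <- min(f - 2L, floor(config$CER * f))
  for (attempt in seq_len(max_attempts)) {
    n_drop_rows <- sample.int(max_row_drop + 1L, 1L) - 1L
    n_drop_cols <- sample.int(max_col_drop + 1L, 1L) - 1L
    rows <- seq_len(n) - 1L
    if (n_drop_rows > 0L) rows <- sort(sample(rows, n - n_drop_rows))
    cols <- seq_len(f) - 1L
    if (n_drop_cols > 0L) cols <- sort(sample(cols, f - n_drop_cols))
    kept <- droplevels(master$labels[rows + 1L])
    if (nlevels(kept) >= 2L && min(table(kept)) >= 2L) {
      return(structure(list(rows = rows, cols = cols),
                       class = "subtable_index"))
    }
  }
  stop("could not sample a valid sub-table (label distribution too degenerate)")
}

#' Materialize a sub-table index against its master
#'
#' @param master a [master_table()].
#' @param index a `subtable_index` (0-based `$rows` / `$cols`).
#' @return a [master_table()] holding the selected rows and columns (label
#'   retained; `row_ids` carry the master's identifiers).
#' @export
materialize_subtable <- function(master, index) {
  stopifnot(inherits(index, "subtable_index"))
  subset_master(master, index$rows, index$cols)
}

#' Build one run's readiness table
#'
#' Samples `config$d` sub-tables and computes, for each, the five quality
#' scores and the three ML accuracies. The result is the readiness space of
#' one run: one record per sub-table, `f_tilde` unset until the mean weight
#' vector exists. A sub-table whose evaluation fails is discarded and
#' resampled.
#'
#' @param master a [master_table()].
#' @param config a [search_config()].
#' @return list of `d` records, each with `$index`, `$quality`,
#'   `$accuracy`, `$f_tilde` (NA).
#' @export
build_readiness_table <- function(master, config = search_config()) {
  records <- vector("list", config$d)
  i <- 1L
  guard <- 0L
  while (i <= config$d) {
    guard <- guard + 1L
    if (guard > 20L * config$d) stop("too many failed sub-table evaluations")
    rec <- tryCatch({
      idx <- sample_subtable(master, config)
      sub <- materialize_subtable(master, idx)
      list(index = idx,
           quality = compute_quality_vector(sub, config),
           accuracy = evaluate_subtable(sub, config),
           f_tilde = NA_real_)
    }, error = function(e) NULL)
    if (!is.null(rec)) {
      records[[i]] <- rec
      i <- i + 1L
    }
  }
  records
}

#' Learn metric weights by forest regression
#'
#' Fits a random-forest regressor (`n_estimators` trees, all features
#' eligible at each split) of the combined accuracy on the five quality
#' scores and returns the impurity-decrease feature importances normalized
#' to unit sum. When the target is constant the importances are undefined
#' and the declared fallback is the uniform vector (0.2 each).
#'
#' @param records list of readiness records (from
#'   [build_readiness_table()]).
#' @param config a [search_config()].
#' @param seed optional integer seed for the forest's bootstrap draws.
#' @return named non-negative numeric vector of length 5 summing to 1.
#' @export
learn_weights <- function(records, config = search_config(), seed = NULL) {
  if (length(records) < 2L) stop("need at least 2 records to learn weights")
  if (!is.null(seed)) set.seed(seed)
  q <- t(vapply(records, `[[`, numeric(5L), "quality"))
  y <- vapply(records, function(r) r$accuracy$combined, numeric(1L))
  if (length(unique(y)) < 2L) {
    w <- rep(0.2, 5L)
  } else {
    w <- cpp_rf_regress_importance(q, y, config$n_estimators, ncol(q))
    if (sum(w) <= 0) w <- rep(0.2, 5L) else w <- w / sum(w)
  }
  names(w) <- quality_metric_names()
  w
}

#' Weighted total quality
#'
#' The readiness score of a (sub-)table: the dot product of its five
#' quality scores with a non-negative, unit-sum weight vector. Both inputs
#' in `[0, 1]` guarantee the result lies in `[0, 1]`.
#'
#' @param quality numeric quality vector of length 5.
#' @param weights numeric weight vector of length 5 (non-negative, summing
#'   to 1; a slack of 1e-3 is allowed so that published weight vectors
#'   rounded to 4 decimals remain usable).
#' @return the weighted total quality.
#' @export
total_quality <- function(quality, weights) {
  if (length(quality) != 5L || length(weights) != 5L)
    stop("quality and weights must both have length 5")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-3) stop("weights must sum to 1")
  sum(quality * weights)
}

#' Random-restart search for the best cleansed sub-table
#'
#' Phase 1 executes `R` independent runs (run `r` is seeded with
#' `config$seed + r`, so results are identical regardless of how many
#' workers execute them): each run samples `d` sub-tables, scores them, and
#' learns its own weight vector. Phase 2 averages the `R` weight vectors
#' into `W*` (renormalized to unit sum), scores every stored record with
#' `W*`, and selects the per-run bests and the global best. Ties are broken
#' by higher combined accuracy, then lower run id, then lower record id.
#'
#' The master's own quality vector, accuracies, and total quality under
#' `W*` are always computed as the raw-data baseline.
#'
#' @param master a [master_table()].
#' @param config a [search_config()]; `config$jobs > 1` forks runs in
#'   parallel.
#' @return an object of class `readiness_search` with fields `records`
#'   (per run), `weights_per_run`, `mean_weights`, `per_run_best`,
#'   `global_best`, `master_baseline`, `config`, `run_seeds`.
#' @export
run_search <- function(master, config = search_config()) {
  stopifnot(inherits(master, "master_table"))
  validate_config(config)
  run_seeds <- config$seed + seq_len(config$R)

  one_run <- function(r) {
    set.seed(run_seeds[r])
    message(sprintf("[run %d/%d] seed %d: sampling %d sub-tables",
                    r, config$R, run_seeds[r], config$d))
    records <- build_readiness_table(master, config)
    w <- learn_weights(records, config)
    message(sprintf("[run %d/%d] done", r, config$R))
    list(records = records, weights = w)
  }

  runs <- if (config$jobs > 1L) {
    res <- parallel::mclapply(seq_len(config$R), one_run,
                              mc.cores = config$jobs, mc.set.seed = FALSE)
    bad <- vapply(res, inherits, logical(1L), "try-error")
    if (any(bad)) {
      stop(sprintf("run(s) %s failed (seeds %s)",
                   paste(which(bad), collapse = ", "),
                   paste(run_seeds[bad], collapse = ", ")))
    }
    res
  } else {
    lapply(seq_len(config$R), one_run)
  }

  wmat <- do.call(rbind, lapply(runs, `[[`, "weights"))
  mean_w <- colMeans(wmat)
  mean_w <- mean_w / sum(mean_w)

  records <- lapply(runs, `[[`, "records")
  for (r in seq_along(records)) {
    for (i in seq_along(records[[r]])) {
      records[[r]][[i]]$f_tilde <-
        total_quality(records[[r]][[i]]$quality, mean_w)
    }
  }

  pick_best <- function(recs) {
    ft <- vapply(recs, `[[`, numeric(1L), "f_tilde")
    acc <- vapply(recs, function(x) x$accuracy$combined, numeric(1L))
    order(-ft, -acc, seq_along(recs))[1L]
  }
  per_run_best <- lapply(seq_along(records), function(r) {
    i <- pick_best(records[[r]])
    list(run = r, record = i, rec = records[[r]][[i]])
  })
  best_ft <- vapply(per_run_best, function(b) b$rec$f_tilde, numeric(1L))
  best_acc <- vapply(per_run_best, function(b) b$rec$accuracy$combined,
                     numeric(1L))
  g <- order(-best_ft, -best_acc, seq_along(per_run_best))[1L]

  set.seed(config$seed)
  baseline_quality <- compute_quality_vector(master, config)
  baseline_accuracy <- evaluate_subtable(master, config)
  master_baseline <- list(
    quality = baseline_quality,
    accuracy = baseline_accuracy,
    f_tilde = total_quality(baseline_quality, mean_w))

  structure(
    list(records = records,
         weights_per_run = wmat,
         mean_weights = mean_w,
         per_run_best = per_run_best,
         global_best = per_run_best[[g]],
         master_baseline = master_baseline,
         config = config,
         run_seeds = run_seeds),
    class = "readiness_search"
  )
}

#' @export
print.readiness_search <- function(x, ...) {
  gb <- x$global_best
  cat(sprintf("<readiness_search> %d run(s) x %d sub-tables\n",
              x$config$R, x$config$d))
  cat(sprintf("  mean weights: %s\n",
              paste(sprintf("%s=%.4f", names(x$mean_weights),
                            x$mean_weights), collapse = " ")))
  cat(sprintf("  master f~ = %.4f; best f~ = %.4f (run %d, %d rows x %d cols)\n",
              x$master_baseline$f_tilde, gb$rec$f_tilde, gb$run,
              length(gb$rec$index$rows), length(gb$rec$index$cols)))
  invisible(x)
}
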