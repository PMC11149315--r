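#' Specification of a synthetic labeled dataset with planted defects
#'
#' Describes a world whose quality defects are known by construction, so
#' every metric and the end-to-end search can be validated without any
#' external data. The generated table consists of
#'
#' * `n_informative_features` Gaussian columns whose class means sit
#'   `class_separation` within-class standard deviations apart (class `c`
#'   gets mean `class_separation / sqrt(2)` on axis `c` modulo the
#'   informative dimension, so any two class means are exactly
#'   `class_separation` apart);
#' * `n_duplicate_features` exact copies of the first informative columns
#'   (planted redundancy for the correlation metrics);
#' * `n_noise_features` independent standard Gaussians (planted
#'   irrelevance);
#' * cell outliers injected at rate `outlier_rate` by shifting a cell away
#'   from the column median by `outlier_magnitude * (3 * MAD + eps)` of its
#'   own column — at any magnitude > 1 the MAD rule detects such a cell by
#'   construction (up to the slight post-injection drift of median and MAD);
#' * MCAR missingness at rate `missing_rate`, restricted to
#'   `n_missing_columns` randomly chosen feature columns (`NULL` = all);
#' * `mislabel_rate` of rows relabeled to a uniformly drawn different
#'   class (geometry untouched: this moves only the class-overlap dial).
#'
#' Outliers are injected before duplication, so duplicate columns remain
#' exact copies; missingness is applied after duplication, so the missing
#' masks of a duplicate and its source differ.
#'
#' @param n_rows,n_informative_features,n_classes shape of the signal.
#' @param class_separation distance between class means, in units of the
#'   within-class standard deviation.
#' @param n_duplicate_features,n_noise_features planted junk columns.
#' @param missing_rate,outlier_rate,mislabel_rate defect rates in `[0, 1)`.
#' @param n_missing_columns how many feature columns carry the missingness
#'   (`NULL` = all).
#' @param outlier_magnitude shift multiplier for injected outliers.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 200L, n_informative_features = 10L,
                           n_classes = 2L, class_separation = 3,
                           n_duplicate_features = 0L, n_noise_features = 0L,
                           missing_rate = 0, n_missing_columns = NULL,
                           outlier_rate = 0, outlier_magnitude = 2,
                           mislabel_rate = 0, seed = 1L) {
  spec <- list(n_rows = as.integer(n_rows),
               n_informative_features = as.integer(n_informative_features),
               n_classes = as.integer(n_classes),
               class_separation = as.numeric(class_separation),
               n_duplicate_features = as.integer(n_duplicate_features),
               n_noise_features = as.integer(n_noise_features),
               missing_rate = as.numeric(missing_rate),
               n_missing_columns = if (is.null(n_missing_columns)) NULL
                                   else as.integer(n_missing_columns),
               outlier_rate = as.numeric(outlier_rate),
               outlier_magnitude = as.numeric(outlier_magnitude),
               mislabel_rate = as.numeric(mislabel_rate),
               seed = as.integer(seed))
  for (rt in c("missing_rate", "outlier_rate", "mislabel_rate")) {
    if (spec[[rt]] < 0 || spec[[rt]] >= 1) stop(sprintf("%s must lie in [0, 1)", rt))
  }
  if (spec$n_classes < 2L) stop("need at least 2 classes")
  if (spec$n_informative_features < 2L) stop("need at least 2 informative features")
  if (spec$n_duplicate_features > spec$n_informative_features)
    stop("cannot plant more duplicates than informative features")
  if (spec$n_rows < spec$n_classes * 2L) stop("too few rows for the class count")
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic master table with ground-truth annotation
#'
#' @param spec a [synthetic_spec()].
#' @return list with `$master` (a [master_table()]) and `$annotation`:
#'   `noise_columns`, `duplicate_columns` (named by their source),
#'   `missing_columns`, `outlier_cells` (row/col data frame, 0-based),
#'   `mislabeled_rows` (0-based), `true_labels`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_rows
  p_inf <- spec$n_informative_features

  labels <- factor(rep_len(paste0("class", seq_len(spec$n_classes)), n),
                   levels = paste0("class", seq_len(spec$n_classes)))
  mu <- matrix(0, spec$n_classes, p_inf)
  for (c in seq_len(spec$n_classes)) {
    axis <- ((c - 1L) %% p_inf) + 1L
    mu[c, axis] <- spec$class_separation / sqrt(2)
  }
  X <- matrix(stats::rnorm(n * p_inf), n, p_inf) + mu[as.integer(labels), ]
  colnames(X) <- sprintf("inf_%02d", seq_len(p_inf))

  # outlier injection on informative columns, before duplication
  outlier_cells <- data.frame(row = integer(), col = integer())
  if (spec$outlier_rate > 0) {
    hit <- which(matrix(stats::runif(n * p_inf) < spec$outlier_rate, n, p_inf),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      med <- matrixStats::colMedians(X)
      mad <- matrixStats::colMedians(abs(sweep(X, 2L, med, "-")))
      shift <- spec$outlier_magnitude * (3 * mad + 1e-6)
      # shift away from the column median so the MAD rule must fire
      dir <- ifelse(X[hit] >= med[hit[, 2L]], 1, -1)
      X[hit] <- X[hit] + dir * shift[hit[, 2L]]
      outlier_cells <- data.frame(row = hit[, 1L] - 1L, col = hit[, 2L] - 1L)
    }
  }

  dup_names <- character()
  if (spec$n_duplicate_features > 0L) {
    src <- seq_len(spec$n_duplicate_features)
    dups <- X[, src, drop = FALSE]
    dup_names <- sprintf("dup_%02d", src)
    colnames(dups) <- dup_names
    names(dup_names) <- colnames(X)[src]
    X <- cbind(X, dups)
  }
  noise_names <- character()
  if (spec$n_noise_features > 0L) {
    noise <- matrix(stats::rnorm(n * spec$n_noise_features), n,
                    spec$n_noise_features)
    noise_names <- sprintf("noise_%02d", seq_len(spec$n_noise_features))
    colnames(noise) <- noise_names
    X <- cbind(X, noise)
  }

  missing_cols <- character()
  if (spec$missing_rate > 0) {
    cand <- seq_len(ncol(X))
    if (!is.null(spec$n_missing_columns)) {
      cand <- sort(sample(cand, min(spec$n_missing_columns, ncol(X))))
    }
    missing_cols <- colnames(X)[cand]
    for (j in cand) {
      X[stats::runif(n) < spec$missing_rate, j] <- NA_real_
    }
  }

  true_labels <- labels
  mislabeled <- integer()
  if (spec$mislabel_rate > 0) {
    flip <- which(stats::runif(n) < spec$mislabel_rate)
    for (i in flip) {
      others <- setdiff(seq_len(spec$n_classes), as.integer(labels[i]))
      labels[i] <- levels(labels)[others[sample.int(length(others), 1L)]]
    }
    mislabeled <- flip - 1L
  }

  master <- master_table(X, labels, label_name = "class")
  list(master = master,
       annotation = list(noise_columns = noise_names,
                         duplicate_columns = dup_names,
                         missing_columns = missing_cols,
                         outlier_cells = outlier_cells,
                         mislabeled_rows = mislabeled,
                         true_labels = true_labels))
}

#' The planted-junk benchmark world
#'
#' The canonical synthetic fixture used by the package's end-to-end tests:
#' 500 rows, 3 Gaussian classes separated by 3 within-class standard
#' deviations on 15 informative features, plus 5 exact duplicates, 10 pure
#' noise columns, 50% MCAR missingness on 6 randomly chosen columns, 2% of
#' cells shifted into MAD-detectable outliers, and 10% mislabeled rows —
#' a 500 x 30 table where roughly half the columns and a tenth of the rows
#' are junk by construction.
#'
#' @param seed integer seed.
#' @param n_rows rows (default 500).
#' @return a [synthetic_spec()].
#' @export
planted_junk_spec <- function(seed = 1L, n_rows = 500L) {
  synthetic_spec(
    n_rows = n_rows, n_informative_features = 15L, n_classes = 3L,
    class_separation = 3, n_duplicate_features = 5L, n_noise_features = 10L,
    missing_rate = 0.5, n_missing_columns = 6L,
    outlier_rate = 0.02, outlier_magnitude = 2,
    mislabel_rate = 0.1, seed = seed)
}

#' Write a synthetic spec or dataset to disk
#'
#' Specs serialize as JSON (for regression fixtures); datasets write via
#' [write_master()] in the same CSV dialect [load_master()] reads.
#'
#' @param spec a [synthetic_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, vals)
}
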