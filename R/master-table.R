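#' Construct a master table
#'
#' A master table is the typed in-memory form of a labeled tabular dataset:
#' an `N x F` numeric feature matrix (missing cells allowed), a categorical
#' label vector, and positional row identifiers. All downstream machinery —
#' quality metrics, ML evaluation, and the sub-table search — operates on
#' this container.
#'
#' @param features numeric matrix (`N x F`); `NA` marks a missing cell.
#' @param labels vector of class labels, length `N`; coerced to factor.
#' @param feature_names character vector of `F` unique column names
#'   (defaults to `colnames(features)`).
#' @param label_name name of the label column (must not collide with a
#'   feature name).
#' @param row_ids integer identifiers, by convention the 0-based positional
#'   indices of the source file; default `0:(N-1)`.
#' @return an object of class `master_table` with fields `features`,
#'   `feature_names`, `labels`, `label_name`, `row_ids`.
#' @export
master_table <- function(features, labels, feature_names = colnames(features),
                         label_name = "label", row_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  f <- ncol(features)
  if (n < 1L) stop("master table needs at least one row")
  if (f < 2L) stop("master table needs at least 2 numeric feature columns")
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(f))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != f) stop("feature_names length must equal ncol(features)")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (label_name %in% feature_names) stop("label_name must not be a feature name")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != n) stop("labels length must equal nrow(features)")
  if (nlevels(labels) < 2L) stop("label column must have at least 2 distinct values")
  if (anyNA(labels)) stop("labels must not contain missing values")
  if (is.null(row_ids)) row_ids <- seq_len(n) - 1L
  colnames(features) <- feature_names
  rownames(features) <- NULL
  structure(
    list(features = features, feature_names = feature_names,
         labels = labels, label_name = label_name,
         row_ids = as.integer(row_ids)),
    class = "master_table"
  )
}

#' @export
print.master_table <- function(x, ...) {
  cat(sprintf("<master_table> %d rows x %d features, label '%s' (%d classes)\n",
              nrow(x$features), ncol(x$features), x$label_name,
              nlevels(x$labels)))
  cat(sprintf("  missing cells: %.1f%%\n",
              100 * mean(is.na(x$features))))
  invisible(x)
}

#' @export
dim.master_table <- function(x) dim(x$features)

# tokens that parse as a missing cell (case-insensitive)
na_tokens <- function() c("", "na", "nan", "null")

parse_numeric_column <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% na_tokens()] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Coerce a raw table to the master-table schema
#'
#' Applies the schema rule used throughout the package: every feature column
#' that is not numeric is dropped (with a warning naming it), standard NA
#' tokens (`""`, `"NA"`, `"NaN"`, `"null"`, case-insensitive) become missing
#' cells, and the designated label column becomes a factor. A column counts
#' as numeric when at least 99% of its non-missing entries parse as numbers;
#' the stray unparseable entries become missing cells. Numeric columns named
#' in `exclude` are dropped as well (clinical exports often carry numeric
#' codes — ages, genotype dosages — that the analyst wants out).
#'
#' Coercion is idempotent: applying it to an already-coerced table is a
#' no-op (apart from `exclude` filtering).
#'
#' @param x a `data.frame` as parsed from CSV, or a `master_table`.
#' @param label_name name of the label column in `x`.
#' @param exclude character vector of additional column names to drop.
#' @return a [master_table()].
#' @export
coerce_schema <- function(x, label_name, exclude = character()) {
  if (inherits(x, "master_table")) {
    keep <- setdiff(x$feature_names, exclude)
    if (length(keep) < 2L) stop("fewer than 2 feature columns remain after exclusion")
    return(master_table(x$features[, keep, drop = FALSE], x$labels,
                        feature_names = keep, label_name = x$label_name,
                        row_ids = x$row_ids))
  }
  x <- as.data.frame(x)
  if (!label_name %in% names(x)) {
    stop(sprintf("label column '%s' not found", label_name))
  }
  raw_labels <- trimws(as.character(x[[label_name]]))
  raw_labels[tolower(raw_labels) %in% na_tokens()] <- NA_character_
  keep_rows <- !is.na(raw_labels)
  if (!all(keep_rows)) {
    warning(sprintf("dropped %d row(s) with missing label", sum(!keep_rows)))
  }
  cand <- setdiff(names(x), c(label_name, exclude))
  cols <- list()
  dropped <- character()
  for (nm in cand) {
    if (is.numeric(x[[nm]])) {  # already typed: no text round trip
      cols[[nm]] <- as.numeric(x[[nm]][keep_rows])
      next
    }
    v <- parse_numeric_column(x[[nm]][keep_rows])
    raw <- trimws(as.character(x[[nm]][keep_rows]))
    non_missing <- !(tolower(raw) %in% na_tokens())
    if (sum(non_missing) == 0L || mean(!is.na(v[non_missing])) >= 0.99) {
      cols[[nm]] <- v
    } else {
      dropped <- c(dropped, nm)
    }
  }
  if (length(dropped)) {
    warning(sprintf("dropped non-numeric column(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  if (length(cols) < 2L) stop("fewer than 2 numeric feature columns after coercion")
  feats <- do.call(cbind, cols)
  master_table(feats, raw_labels[keep_rows],
               feature_names = names(cols), label_name = label_name,
               row_ids = (which(keep_rows) - 1L))
}

#' Load a master table from CSV
#'
#' Reads a delimited text file with a header row and coerces it via
#' [coerce_schema()]. Row identifiers are the 0-based positional indices of
#' the data rows in the input file, and are carried through every report.
#'
#' @param path path to the CSV file.
#' @param label_name name of the class-label column.
#' @param delim field delimiter (default comma).
#' @param exclude optional character vector of column names to drop even if
#'   numeric.
#' @return a [master_table()].
#' @export
load_master <- function(path, label_name, delim = ",", exclude = character()) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, sep = delim, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  coerce_schema(raw, label_name, exclude = exclude)
}

#' Write a master table to CSV
#'
#' Serializes features plus the label column with full double precision
#' (`%.17g`), so that a write/load round trip reproduces values, names, and
#' the missingness mask exactly. Missing cells are written as empty fields.
#'
#' @param x a [master_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_master <- function(x, path) {
  stopifnot(inherits(x, "master_table"))
  fmt <- function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  }
  cells <- vapply(seq_len(ncol(x$features)),
                  function(j) fmt(x$features[, j]),
                  character(nrow(x$features)))
  cells <- matrix(cells, nrow = nrow(x$features))
  df <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(df) <- x$feature_names
  df[[x$label_name]] <- as.character(x$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# materialized sub-table: rows/cols are 0-based indices into the master
subset_master <- function(master, rows, cols) {
  master_table(master$features[rows + 1L, cols + 1L, drop = FALSE],
               master$labels[rows + 1L],
               feature_names = master$feature_names[cols + 1L],
               label_name = master$label_name,
               row_ids = master$row_ids[rows + 1L])
}
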