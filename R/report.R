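#' Compact range strings for index sets
#'
#' Reports store row/column index sets as compact 0-based range strings,
#' e.g. `c(0,1,2,3,4,7,9)` becomes `"0-4,7,9"`. `decode_ranges()` inverts
#' the encoding.
#'
#' @param idx strictly increasing non-negative integer vector.
#' @return `encode_ranges()`: a single string; `decode_ranges()`: an
#'   integer vector.
#' @export
encode_ranges <- function(idx) {
  if (length(idx) == 0L) return("")
  idx <- as.integer(idx)
  brk <- c(0L, which(diff(idx) != 1L), length(idx))
  parts <- vapply(seq_len(length(brk) - 1L), function(i) {
    lo <- idx[brk[i] + 1L]
    hi <- idx[brk[i + 1L]]
    if (lo == hi) as.character(lo) else sprintf("%d-%d", lo, hi)
  }, character(1L))
  paste(parts, collapse = ",")
}

#' @rdname encode_ranges
#' @param s a range string.
#' @export
decode_ranges <- function(s) {
  if (!nzchar(s)) return(integer())
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      lohi <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      seq.int(lohi[1L], lohi[2L])
    } else as.integer(p)
  })
  as.integer(unlist(out))
}

fmt6 <- function(x) sprintf("%.6f", x)

record_row <- function(run, i, rec) {
  data.frame(
    run = run, record = i,
    n_rows = length(rec$index$rows), n_cols = length(rec$index$cols),
    pc_q = fmt6(rec$quality[["pc"]]),
    spearman_q = fmt6(rec$quality[["spearman"]]),
    missing_q = fmt6(rec$quality[["missing"]]),
    outlier_q = fmt6(rec$quality[["outlier"]]),
    overlap_q = fmt6(rec$quality[["overlap"]]),
    clf_acc = fmt6(rec$accuracy$classification),
    clu_acc = fmt6(rec$accuracy$clustering),
    combined_acc = fmt6(rec$accuracy$combined),
    f_tilde = fmt6(rec$f_tilde),
    rows = encode_ranges(rec$index$rows),
    cols = encode_ranges(rec$index$cols),
    stringsAsFactors = FALSE)
}

#' Write the report bundle of a finished search
#'
#' Persists, under `outdir`:
#' * `run_<r>.csv` — one CSV per run holding that run's readiness records
#'   (five quality scores, three accuracies, total quality, and the
#'   row/column index sets as range strings);
#' * `best_per_run.csv` — the best record of each run;
#' * `cleansed.csv` — the global best sub-table materialized from the
#'   master (features plus label column);
#' * `summary.txt` — global best metadata: run id, total quality, selected
#'   row indices and column names/indices, the mean weight vector, and the
#'   master baseline.
#'
#' Floats are serialized at 6 decimals; all indices are 0-based. If any
#' target file already exists, the bundle is written into a timestamped
#' subdirectory instead of overwriting.
#'
#' @param result a `readiness_search` (from [run_search()]).
#' @param master the [master_table()] the search ran on.
#' @param outdir output directory (created if needed).
#' @return an object of class `report_bundle` listing the written paths.
#' @export
write_reports <- function(result, master, outdir) {
  stopifnot(inherits(result, "readiness_search"),
            inherits(master, "master_table"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create output directory: %s", outdir))
  probe <- file.path(outdir, "summary.txt")
  if (file.exists(probe)) {
    outdir <- file.path(outdir, format(Sys.time(), "%Y%m%d-%H%M%S"))
    dir.create(outdir, recursive = TRUE)
  }

  per_run <- character(result$config$R)
  for (r in seq_len(result$config$R)) {
    rows <- do.call(rbind, lapply(seq_along(result$records[[r]]), function(i)
      record_row(r, i, result$records[[r]][[i]])))
    per_run[r] <- file.path(outdir, sprintf("run_%02d.csv", r))
    utils::write.csv(rows, per_run[r], row.names = FALSE, quote = TRUE)
  }

  best_rows <- do.call(rbind, lapply(result$per_run_best, function(b)
    record_row(b$run, b$record, b$rec)))
  best_path <- file.path(outdir, "best_per_run.csv")
  utils::write.csv(best_rows, best_path, row.names = FALSE, quote = TRUE)

  gb <- result$global_best
  cleansed <- materialize_subtable(master, gb$rec$index)
  cleansed_path <- file.path(outdir, "cleansed.csv")
  write_master(cleansed, cleansed_path)

  mb <- result$master_baseline
  summary_path <- file.path(outdir, "summary.txt")
  lines <- c(
    "# readiness search summary (all indices 0-based)",
    sprintf("best_run: %d", gb$run),
    sprintf("best_record: %d", gb$record),
    sprintf("best_f_tilde: %s", fmt6(gb$rec$f_tilde)),
    sprintf("best_n_rows: %d", length(gb$rec$index$rows)),
    sprintf("best_n_cols: %d", length(gb$rec$index$cols)),
    sprintf("best_quality: %s", paste(fmt6(gb$rec$quality), collapse = " ")),
    sprintf("best_classification_accuracy: %s", fmt6(gb$rec$accuracy$classification)),
    sprintf("best_clustering_accuracy: %s", fmt6(gb$rec$accuracy$clustering)),
    sprintf("mean_weights: %s", paste(fmt6(result$mean_weights), collapse = " ")),
    sprintf("master_quality: %s", paste(fmt6(mb$quality), collapse = " ")),
    sprintf("master_classification_accuracy: %s", fmt6(mb$accuracy$classification)),
    sprintf("master_clustering_accuracy: %s", fmt6(mb$accuracy$clustering)),
    sprintf("master_f_tilde: %s", fmt6(mb$f_tilde)),
    sprintf("selected_columns_names: %s",
            paste(master$feature_names[gb$rec$index$cols + 1L], collapse = ",")),
    sprintf("selected_columns: %s", encode_ranges(gb$rec$index$cols)),
    sprintf("selected_rows: %s", encode_ranges(gb$rec$index$rows)))
  writeLines(lines, summary_path)

  structure(
    list(per_run_tables = per_run, best_per_run = best_path,
         cleansed_csv = cleansed_path, summary_txt = summary_path,
         outdir = outdir),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  ", x$summary_txt, "\n", sep = "")
  cat("  ", x$cleansed_csv, "\n", sep = "")
  cat(sprintf("  %d per-run CSV(s), %s\n",
              length(x$per_run_tables), x$best_per_run))
  invisible(x)
}
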