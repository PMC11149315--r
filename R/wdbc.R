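#' Load the bundled Wisconsin Diagnosis Breast Cancer table
#'
#' The public WDBC dataset (569 fine-needle-aspirate image records, 30
#' numeric features, binary `diagnosis` label: `M` malignant / `B`
#' benign) ships with the package as plain-text CSV, split into chunks to
#' keep individual files small. It is the one real dataset small enough to
#' serve as a deterministic reference for the quality metrics: it has no
#' missing values, a known feature-correlation structure, and a class
#' geometry in which exactly 39 of 569 samples are overlapped under the
#' default k = 7, theta = 3 neighbourhood rule.
#'
#' @return a [master_table()] with `N = 569`, `F = 30`.
#' @export
load_wdbc <- function() {
  dir <- system.file("extdata", "wdbc", package = "tabready", mustWork = TRUE)
  files <- sort(list.files(dir, pattern = "^wdbc-.*\\.csv$", full.names = TRUE))
  parts <- lapply(files, utils::read.csv, colClasses = "character",
                  check.names = FALSE, na.strings = NULL)
  coerce_schema(do.call(rbind, parts), "diagnosis")
}
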