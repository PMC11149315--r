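# Independent oracles: deliberately naive implementations of the textbook
# formulas, used to cross-check the package's optimized code paths.

# Pearson coefficient by direct summation on pairwise-complete observations;
# NA when undefined (constant column, < 2 complete pairs)
oracle_pair_pearson <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  a <- a[both]; b <- b[both]
  if (length(a) < 2L) return(NA_real_)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  if (den == 0) NA_real_ else num / den
}

# 1 - mean |coefficient| over all unordered pairs; undefined pairs count 0
oracle_corr_quality <- function(m, rank_first = FALSE) {
  p <- ncol(m)
  tot <- 0
  for (j in seq_len(p - 1L)) {
    for (k in seq.int(j + 1L, p)) {
      a <- m[, j]; b <- m[, k]
      both <- !is.na(a) & !is.na(b)
      a <- a[both]; b <- b[both]
      if (rank_first && length(a) >= 2L) { a <- rank(a); b <- rank(b) }
      r <- oracle_pair_pearson(a, b)
      if (!is.na(r)) tot <- tot + abs(r)
    }
  }
  1 - tot / (p * (p - 1) / 2)
}

# exhaustive O(N^2) class-overlap R: full distance sort per sample, ties by
# ascending row index, foreign count among the k nearest, overlap iff > theta
oracle_overlap_r <- function(m, labels, k = 7L, theta = 3) {
  n <- nrow(m)
  over <- logical(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(m) - m[i, ])^2)
    d2[i] <- Inf
    nb <- order(d2, seq_len(n))[seq_len(k)]
    over[i] <- sum(labels[nb] != labels[i]) > theta
  }
  mean(over)
}

# direct evaluation of the silhouette formula
oracle_silhouette <- function(m, cl) {
  n <- nrow(m)
  dmat <- as.matrix(stats::dist(m))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(c) mean(dmat[i, cl == c]), numeric(1L)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# tiny two-blob master: two tight well-separated Gaussian classes
two_blob_master <- function(n = 60L, p = 4L, sep = 30, seed = 1L) {
  set.seed(seed)
  half <- n %/% 2L
  x <- rbind(matrix(rnorm(half * p), half, p),
             matrix(rnorm((n - half) * p, mean = sep), n - half, p))
  master_table(x, rep(c("a", "b"), c(half, n - half)),
               feature_names = paste0("f", seq_len(p)))
}

# small noisy fixture for fast search tests
small_junk_spec <- function(seed = 1L) {
  synthetic_spec(n_rows = 150L, n_informative_features = 6L, n_classes = 2L,
                 class_separation = 2.5, n_duplicate_features = 2L,
                 n_noise_features = 4L, missing_rate = 0.3,
                 n_missing_columns = 3L, outlier_rate = 0.02,
                 mislabel_rate = 0.1, seed = seed)
}

write_toy_csv <- function(path, n = 40L, seed = 7L) {
  set.seed(seed)
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                   y = rep(c("u", "v"), length.out = n))
  utils::write.csv(df, path, row.names = FALSE)
  path
}
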