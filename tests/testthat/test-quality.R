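test_that("correlation qualities match the brute-force pair loops", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 4), 8, 4)
    if (seed > 2) m[sample(length(m), 6)] <- NA  # exercise pairwise-complete
    expect_equal(pearson_quality(m), oracle_corr_quality(m), tolerance = 1e-12)
    expect_equal(spearman_quality(m),
                 oracle_corr_quality(m, rank_first = TRUE), tolerance = 1e-12)
  }
})

test_that("spearman equals the tie-free rank-difference formula", {
  set.seed(3)
  m <- matrix(sample(1000, 18), 6, 3)  # distinct values: no ties
  rho_pair <- function(a, b) {
    d <- rank(a) - rank(b)
    1 - 6 * sum(d^2) / (length(a) * (length(a)^2 - 1))
  }
  expected <- 1 - mean(abs(c(rho_pair(m[, 1], m[, 2]),
                             rho_pair(m[, 1], m[, 3]),
                             rho_pair(m[, 2], m[, 3]))))
  expect_equal(spearman_quality(m), expected, tolerance = 1e-12)
})

test_that("correlation limits and invariances hold", {
  set.seed(4)
  x <- rnorm(30)
  expect_equal(pearson_quality(cbind(x, x)), 0, tolerance = 1e-12)
  # strictly monotone transform: |rho| = 1 although Pearson |r| < 1
  expect_equal(spearman_quality(cbind(x, exp(x))), 0, tolerance = 1e-12)
  expect_lt(0, pearson_quality(cbind(x, exp(3 * x))))
  # affine invariance of |r|
  m <- matrix(rnorm(40), 20, 2)
  expect_equal(pearson_quality(m),
               pearson_quality(cbind(-3 * m[, 1] + 7, m[, 2])),
               tolerance = 1e-12)
  # constant column contributes zero correlation
  expect_equal(pearson_quality(cbind(m, 5)),
               1 - (1 - pearson_quality(m)) / 3, tolerance = 1e-12)
})

test_that("appending a duplicate feature never increases pc_quality", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(25 * 4), 25, 4)
    expect_lte(pearson_quality(cbind(m, dup = m[, 1])), pearson_quality(m))
  }
})

test_that("missing_quality is the exact complement of the missing fraction", {
  m <- matrix(1, 4, 3)
  m[c(1, 5, 9)] <- NA
  expect_identical(missing_quality(m), 0.75)
  expect_identical(missing_quality(matrix(rnorm(12), 4, 3)), 1)
  for (seed in 1:3) {
    set.seed(seed)
    x <- matrix(rnorm(50), 10, 5)
    x[runif(50) < 0.3] <- NA
    expect_equal(missing_quality(x) + mean(is.na(x)), 1, tolerance = 1e-15)
  }
})

test_that("outlier_quality implements the MAD rule", {
  # hand-evaluated single column: median 5.5, MAD 2.5, only 1000 flagged
  col <- c(1:9, 1000)
  rep <- outlier_quality(matrix(col, ncol = 1))
  expect_equal(rep$medians, 5.5)
  expect_equal(rep$mads, 2.5)
  expect_equal(rep$flagged_row_count, 1L)
  expect_equal(rep$score, 0.9)
  expect_true(rep$flags[10, 1] && sum(rep$flags) == 1L)

  # constant columns: MAD = 0 flags nothing
  expect_equal(outlier_quality(matrix(3, 10, 4))$score, 1)

  # tight sample where no deviation crosses 3 MAD
  expect_equal(outlier_quality(matrix(rep(c(1, 2, 3), 5), ncol = 1))$score, 1)

  # missing cells are never flagged
  x <- matrix(c(1:9, NA), ncol = 1)
  expect_equal(outlier_quality(x)$score, 1)
})

test_that("class overlap equals the exhaustive O(N^2) oracle", {
  # integer 1-D instance with heavy distance ties
  set.seed(9)
  m1 <- matrix(as.numeric(sample(0:7, 16, replace = TRUE)), ncol = 1)
  l1 <- factor(sample(c("a", "b"), 16, replace = TRUE))
  r1 <- class_overlap_quality(m1, l1, knn_k = 7, knn_theta = 3)
  expect_equal(r1$r_value, oracle_overlap_r(m1, l1), tolerance = 1e-15)

  # random instances up to N = 200, both continuous and gridded
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(50:200, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    if (seed %% 2 == 0) m <- round(m)  # force ties
    l <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
    got <- class_overlap_quality(m, l, knn_k = 7, knn_theta = 3)
    expect_equal(got$r_value, oracle_overlap_r(m, l), tolerance = 1e-15)
    expect_equal(got$score, 1 - got$r_value)
  }
})

test_that("far-separated blobs have zero overlap", {
  m <- two_blob_master()
  rep <- class_overlap_quality(m)
  expect_equal(rep$score, 1)
  expect_true(all(rep$foreign_counts[1:7] == 0))
})

test_that("quality vector has fixed order, range, and permutation invariance", {
  gen <- generate_dataset(small_junk_spec(seed = 2))
  m <- gen$master
  q <- compute_quality_vector(m)
  expect_named(q, c("pc", "spearman", "missing", "outlier", "overlap"))
  expect_true(all(q >= 0 & q <= 1))
  expect_identical(q, compute_quality_vector(m))

  set.seed(5)
  rp <- sample(nrow(m$features))
  cp <- sample(ncol(m$features))
  m_perm <- master_table(m$features[rp, cp], m$labels[rp],
                         feature_names = m$feature_names[cp],
                         label_name = m$label_name)
  expect_equal(compute_quality_vector(m_perm), q, tolerance = 1e-12)
})

test_that("quality metric preconditions raise errors", {
  expect_error(pearson_quality(matrix(1:5, ncol = 1)), "at least 2")
  expect_error(outlier_quality(matrix(NA_real_, 3, 2)), "missing")
  expect_error(class_overlap_quality(matrix(rnorm(10), 5, 2),
                                     factor(rep("a", 5))), "2 classes")
  expect_error(class_overlap_quality(matrix(rnorm(10), 5, 2),
                                     factor(c("a", "a", "b", "b", "a")),
                                     knn_k = 7), "knn_k")
})
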