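test_that("sparsity reduction applies the at-least-percentage rule", {
  v <- matrix(NA_real_, 3, 4, dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  v["P1", ] <- 1               # 4/4 observed
  v["P2", 1:3] <- 1            # 3/4
  v["P3", 1:2] <- 1            # 2/4
  m <- QuantMatrix(v)
  expect_equal(qm_proteins(sparsity_reduce(m, "SR75")), c("P1", "P2"))  # 0.75*4 = 3
  expect_equal(qm_proteins(sparsity_reduce(m, 0)), qm_proteins(m))      # NoSR identity
  complete <- toy_qm(matrix(1, 5, 4))
  expect_identical(qm_values(sparsity_reduce(complete, "SR90")), qm_values(complete))
  expect_warning(sparsity_reduce(m[3, ], "SR90"), "removed all")
})

test_that("stricter sparsity thresholds retain nested protein subsets", {
  m <- sim_small()$matrix
  sets <- lapply(c("NoSR", "SR66", "SR75", "SR90"),
                 function(sr) qm_proteins(sparsity_reduce(m, sr)))
  for (i in 1:3) expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("row-statistic imputation fills the documented values and errors on empty rows", {
  m <- toy_qm(matrix(c(4, NA, 8), 1, 3))
  expect_equal(unname(qm_values(impute(m, "HalfRowMin"))[1, ]), c(4, 2, 8))
  expect_equal(unname(qm_values(impute(m, "RowMean"))[1, ]), c(4, 6, 8))
  expect_equal(unname(qm_values(impute(m, "RowMedian"))[1, ]), c(4, 6, 8))
  expect_equal(unname(qm_values(impute(m, "Zero"))[1, ]), c(4, 0, 8))
  empty <- toy_qm(matrix(NA_real_, 2, 3))
  expect_error(impute(empty, "RowMean"), "sparsity reduction")
})

test_that("no imputation method alters an observed entry", {
  set.seed(8)
  v <- matrix(2^rnorm(20 * 6, 8), 20, 6)
  v[sample(length(v), 15)] <- NA
  m <- toy_qm(v)
  obs <- !is.na(v)
  for (method in c("Zero", "HalfRowMin", "RowMean", "RowMedian", "KNN",
                   "IterativeSVD", "SoftImpute")) {
    out <- qm_values(impute(m, method))
    expect_false(anyNA(out))
    expect_identical(out[obs], v[obs])
  }
})

test_that("KNN matches a brute-force distance-weighted neighbor oracle", {
  set.seed(3)
  v <- matrix(rnorm(5 * 4, 10), 5, 4)
  v[2, 3] <- NA
  m <- toy_qm(v)
  got <- qm_values(impute(m, "KNN", k = 2))[2, 3]
  # oracle: Euclidean distance on mutually observed columns, rescaled to the
  # full column count, over rows observed in column 3
  shared <- c(1, 2, 4)
  d <- sapply(c(1, 3, 4, 5), function(i)
    sqrt(sum((v[2, shared] - v[i, shared])^2) / length(shared) * ncol(v)))
  cand <- c(1, 3, 4, 5)[order(d)][1:2]
  w <- 1 / sort(d)[1:2]
  expect_equal(got, sum(w * v[cand, 3]) / sum(w), tolerance = 1e-10)
})

test_that("SVD-based methods recover a low-rank matrix and fix complete ones", {
  set.seed(4)
  u <- matrix(rnorm(30 * 2), 30, 2); w <- matrix(rnorm(2 * 10), 2, 10)
  low <- u %*% w + 20   # rank 3: rank-2 signal plus the constant offset
  holes <- low; holes[sample(length(low), 30)] <- NA
  m <- toy_qm(holes)
  miss <- is.na(holes)
  rec <- qm_values(impute(m, "IterativeSVD", rank = 3, tol = 1e-6))
  expect_lt(mean(abs(rec[miss] - low[miss])), 0.01)
  # soft thresholding trades exactness for shrinkage; small shrinkage is near-exact
  soft <- qm_values(impute(m, "SoftImpute", shrinkage = 0.5))
  expect_lt(mean(abs(soft[miss] - low[miss])), 0.3)
  expect_gt(cor(soft[miss], low[miss]), 0.97)
  complete <- toy_qm(low)
  expect_identical(qm_values(impute(complete, "SoftImpute")), qm_values(complete))
})

test_that("sum normalization equalizes column sums to the mean original sum", {
  m <- toy_qm(cbind(S1 = c(1, 3), S2 = c(2, 6)))
  out <- qm_values(normalize_quant(m, "Sum"))
  expect_equal(unname(out[, "S1"]), c(1.5, 4.5))
  expect_equal(unname(out[, "S2"]), c(1.5, 4.5))
  big <- qm_values(normalize_quant(toy_qm(matrix(runif(50 * 8, 1, 100), 50, 8)), "Sum"))
  cs <- colSums(big)
  expect_lt(diff(range(cs)) / mean(cs), 1e-9)
})

test_that("median normalization equalizes column medians", {
  set.seed(1)
  m <- toy_qm(matrix(runif(30 * 5, 1, 50), 30, 5))
  out <- qm_values(normalize_quant(m, "Median"))
  med <- apply(out, 2, median)
  expect_lt(diff(range(med)) / mean(med), 1e-9)
  zero <- toy_qm(matrix(c(0, 0, 1, 2), 2, 2))
  expect_error(normalize_quant(zero, "Median"), "zero column median")
})

test_that("quantile normalization gives every column identical sorted values", {
  set.seed(2)
  m <- toy_qm(matrix(2^rnorm(40 * 6, 8), 40, 6))
  out <- qm_values(normalize_quant(m, "QN"))
  sorted <- apply(out, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  expect_error(normalize_quant(toy_qm(matrix(c(1, NA), 1, 2)), "QN"), "complete")
})

test_that("TRQN equals QN off the tail and rescales the top fraction", {
  set.seed(6)
  m <- toy_qm(matrix(2^rnorm(100 * 4, 8), 100, 4))
  qn <- qm_values(normalize_quant(m, "QN"))
  tr <- qm_values(normalize_quant(m, "TRQN", tail_fraction = 0.05))
  v <- qm_values(m)
  for (j in 1:4) {
    tail_idx <- order(v[, j], decreasing = TRUE)[1:5]
    expect_equal(tr[-tail_idx, j], qn[-tail_idx, j])
    ratio <- median(v[tail_idx, j] / qn[tail_idx, j])
    expect_equal(tr[tail_idx, j], qn[tail_idx, j] * ratio)
  }
  expect_identical(qm_values(normalize_quant(m, "Unnorm")), v)
})

test_that("log transform is log2(x+1) with its closed-form values", {
  k <- 1:10
  m <- toy_qm(matrix(c(0, 3, 2^k - 1), 1, 12))
  out <- qm_values(log_transform(m))
  expect_equal(unname(out[1, ]), c(0, 2, k))
  neg <- toy_qm(matrix(-1, 1, 1), log2_scale = TRUE)
  expect_error(log_transform(neg), "negative")
})
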