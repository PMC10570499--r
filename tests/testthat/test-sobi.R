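test_that("lag conversion rounds to samples, deduplicates, and bounds-checks", {
  expect_identical(lags_to_samples(c(1, 2, 3, 4), 500), c(1L, 2L))
  expect_identical(lags_to_samples(c(10, 12, 20), 500, 1000), c(5L, 6L, 10L))
  full <- lags_to_samples(default_lags_ms(), 500)
  expect_false(is.unsorted(full, strictly = TRUE))
  expect_equal(range(full), c(1L, 175L))          # 1 ms .. 350 ms at 500 Hz
  expect_false(anyDuplicated(full) > 0)
  expect_error(lags_to_samples(c(-1, 5), 500), "positive")
  expect_error(lags_to_samples(400, 500, 100), "below the record length")
})

test_that("lagged covariances match the direct summation oracle", {
  set.seed(7)
  x <- matrix(rnorm(3 * 400), 3)
  lags <- c(2L, 7L)
  cc <- lagged_covariances(x, lags)
  xc <- x - rowMeans(x)
  T <- 400L - 7L
  for (l in lags) {
    M <- matrix(0, 3, 3)
    for (t in seq_len(T)) M <- M + tcrossprod(xc[, t], xc[, t + l])
    M <- M / T
    expect_equal(cc[[as.character(l)]], (M + t(M)) / 2, tolerance = 1e-12)
    expect_equal(cc[[as.character(l)]], t(cc[[as.character(l)]]))
  }
  expect_error(lagged_covariances(x, 400L), ">= sample count")
})

test_that("white noise has no lag structure; whitened data has identity at lag 0", {
  set.seed(8)
  x <- matrix(rnorm(4 * 50000), 4)
  C <- lagged_covariances(x, 10L)[[1]]
  expect_lt(max(abs(C)), 5 / sqrt(50000))
  wh <- whiten(x)
  C0 <- lagged_covariances(wh$z, 0L)[[1]]
  expect_equal(C0, diag(4), tolerance = 1e-8)
})

test_that("whitening reports rank and inverts on the retained subspace", {
  set.seed(9)
  x <- matrix(rnorm(4 * 2000), 4)
  wh <- whiten(x)
  expect_equal(wh$rank, 4L)
  expect_equal(tcrossprod(wh$z) / ncol(x), diag(4), tolerance = 1e-8)
  expect_equal(wh$dewhiten %*% wh$K %*% (x - wh$center), x - wh$center,
               tolerance = 1e-8)
  # rank-2 data embedded in 4 channels
  base <- matrix(rnorm(2 * 2000), 2)
  x2 <- rbind(base, base[1, ] + base[2, ], base[1, ] - 2 * base[2, ])
  expect_equal(whiten(x2)$rank, 2L)
})

test_that("joint diagonalization exactly recovers a commuting construction", {
  set.seed(10)
  n <- 6
  Q <- random_orthogonal(n)
  mats <- lapply(1:5, function(k) {
    d <- rnorm(n)
    M <- Q %*% diag(d) %*% t(Q)
    (M + t(M)) / 2
  })
  jd <- joint_diagonalize(mats)
  expect_true(jd$converged)
  expect_lt(tail(jd$criterion, 1), 1e-12)
  expect_equal(crossprod(jd$V), diag(n), tolerance = 1e-10)
  # V equals Q up to column permutation and sign
  M <- abs(crossprod(jd$V, Q))
  expect_lt(max(abs(M[M > 0.5] - 1)), 1e-8)
  expect_equal(colSums(M > 0.5), rep(1L, n), ignore_attr = TRUE)
  # criterion never increases across sweeps
  expect_true(all(diff(jd$criterion) <= 1e-12))
})

test_that("joint diagonalization degenerates gracefully", {
  # single symmetric matrix: reduces to an eigendecomposition
  set.seed(11)
  A <- crossprod(matrix(rnorm(25), 5))
  jd <- joint_diagonalize(list(A))
  D <- t(jd$V) %*% A %*% jd$V
  # residual off-diagonal mass is bounded by the rotation tolerance times
  # the matrix scale
  expect_lt(max(abs(D - diag(diag(D)))) / max(abs(A)), 1e-7)
  expect_equal(sort(diag(D)), sort(eigen(A, symmetric = TRUE)$values),
               tolerance = 1e-10)
  # identity matrices only: nothing to rotate
  jd2 <- joint_diagonalize(list(diag(4), diag(4)))
  expect_equal(jd2$V, diag(4))
  expect_equal(tail(jd2$criterion, 1), 0)
  # non-symmetric input is rejected
  B <- matrix(rnorm(16), 4)
  expect_error(joint_diagonalize(list(B)), "not symmetric")
})

test_that("SOBI separates AR sources mixed by a known matrix", {
  set.seed(12)
  N <- 10000                            # 20 s at 500 Hz
  S <- ar_sources(6, N)
  A <- matrix(rnorm(36), 6)
  rec <- eeg_recording(A %*% S, 500)
  dec <- sobi(rec)
  expect_lt(amari_index(dec$W %*% A), 0.1)
  expect_gt(min(match_components(dec$S, S)$abs_cor), 0.95)
  # reconstruction of the (full-rank) input
  xc <- rec$data - dec$center
  expect_lt(norm(dec$A %*% dec$S - xc, "F") / norm(xc, "F"), 1e-6)
  # W A = I and unit-norm mixing columns under the package convention
  expect_equal(dec$W %*% dec$A, diag(6), tolerance = 1e-8)
  expect_equal(colSums(dec$A^2), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(diff(dec$jd$criterion) <= 1e-12))
})

test_that("SOBI under identity mixing returns the sources themselves", {
  set.seed(13)
  S <- ar_sources(4, 8000)
  dec <- sobi(eeg_recording(S, 500))
  m <- match_components(dec$S, S)
  expect_gt(min(m$abs_cor), 0.99)
})

test_that("SOBI is equivariant under invertible channel transforms", {
  set.seed(14)
  S <- ar_sources(5, 10000)
  A <- matrix(rnorm(25), 5)
  M <- matrix(rnorm(25), 5) + 3 * diag(5)
  dec2 <- sobi(eeg_recording(M %*% A %*% S, 500))
  expect_lt(amari_index(dec2$W %*% (M %*% A)), 0.05)
})

test_that("amari index is zero exactly on scaled permutations", {
  P <- diag(c(2, -3, 0.5))[c(2, 3, 1), ]
  expect_equal(amari_index(P), 0)
  expect_gt(amari_index(matrix(1, 3, 3)), 0.5)
  expect_error(amari_index(matrix(1, 2, 3)), "square")
})
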