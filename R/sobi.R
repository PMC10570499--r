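#' Default SOBI lag set (ms)
#'
#' The 41 time delays, in milliseconds, over which lagged covariances are
#' jointly diagonalized. The set spans 1-350 ms: dense at short delays where
#' the autocorrelation carries most structure, sparser toward the tail.
#'
#' @return numeric vector of 41 delays in ms.
#' @export
default_lags_ms <- function() {
  c(1:10, seq(12, 20, by = 2), seq(25, 100, by = 5), seq(125, 350, by = 25))
}

#' Convert lags in ms to sample lags
#'
#' Rounds each delay to the nearest sample (minimum 1), deduplicates, and
#' sorts. Errors if a lag reaches or exceeds the record length.
#'
#' @param lags_ms positive delays in ms.
#' @param srate sampling rate (Hz).
#' @param n_samples record length, for bounds checking (optional).
#' @return strictly increasing integer sample lags.
#' @export
lags_to_samples <- function(lags_ms, srate, n_samples = NULL) {
  if (any(lags_ms <= 0)) stop("lags must be strictly positive")
  lag <- sort(unique(pmax(1L, as.integer(round(lags_ms * srate / 1000)))))
  if (!is.null(n_samples) && max(lag) >= n_samples)
    stop("maximum lag (", max(lag), " samples) must be below the record length (",
         n_samples, ")")
  lag
}

#' Time-lagged covariance matrices
#'
#' For mean-removed data `x` (channels x samples) returns, for each sample lag
#' tau, the symmetrized lagged covariance
#' \eqn{\frac{1}{2}(C(\tau) + C(\tau)^T)} with
#' \eqn{C(\tau) = \frac{1}{T}\sum_t x(t) x(t+\tau)^T} (biased 1/T
#' normalization). All lags share a common summation window of
#' `T = N - max(lags)` samples so the estimates are directly comparable and
#' can be computed in a handful of BLAS calls.
#'
#' @param x numeric matrix, channels x samples (mean is removed internally).
#' @param lags integer sample lags (>= 0).
#' @param symmetrize logical; return the symmetric part (default `TRUE`).
#' @return named list of n x n matrices, one per lag.
#' @export
lagged_covariances <- function(x, lags, symmetrize = TRUE) {
  x <- as.matrix(x)
  N <- ncol(x)
  lags <- as.integer(lags)
  if (any(lags < 0)) stop("lags must be non-negative")
  if (max(lags) >= N) stop("lag ", max(lags), " >= sample count ", N)
  x <- x - rowMeans(x)
  cube <- lagged_cov_cpp(x, as.numeric(lags))
  out <- lapply(seq_along(lags), function(k) {
    C <- cube[, , k]
    if (symmetrize) (C + t(C)) / 2 else C
  })
  names(out) <- as.character(lags)
  out
}

#' Spatial whitening
#'
#' Projects mean-removed data onto the principal subspace and rescales it so
#' the zero-lag covariance is the identity. Rank deficiency is handled by
#' dropping eigenvalues below `rank_tol` times the largest.
#'
#' @param x channels x samples matrix.
#' @param rank_tol relative eigenvalue cutoff.
#' @return list with `z` (rank x samples whitened data), `K` (rank x n
#'   whitening transform), `dewhiten` (n x rank right inverse of `K`),
#'   `rank`, and `center` (channel means).
#' @export
whiten <- function(x, rank_tol = 1e-12) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("whiten: non-finite values in input")
  center <- rowMeans(x)
  xc <- x - center
  C0 <- tcrossprod(xc) / ncol(xc)
  e <- eigen(C0, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * rank_tol)
  if (rank < 1L) stop("whiten: zero-variance data")
  d <- e$values[seq_len(rank)]
  E <- e$vectors[, seq_len(rank), drop = FALSE]
  K <- t(E) / sqrt(d)                    # rank x n
  list(z = K %*% xc, K = K, dewhiten = E * rep(sqrt(d), each = nrow(E)),
       rank = rank, center = center)
}

#' Joint approximate diagonalization
#'
#' Finds one orthogonal matrix `V` that simultaneously (approximately)
#' diagonalizes a set of symmetric matrices by Givens-rotation sweeps,
#' minimizing the summed squared off-diagonal entries of
#' \eqn{V^T C_k V}.
#'
#' Convergence is declared when every rotation angle in a sweep falls below
#' `tol` (radians), when the set is diagonalized to numerical precision, or when a
#' full sweep reduces the criterion by less than `crit_tol` times its
#' current value (a plateau: near-degenerate directions keep producing
#' finite rotations that no longer improve the fit).
#'
#' @param mats list of symmetric matrices with a common dimension.
#' @param tol rotation-angle convergence threshold (radians).
#' @param max_sweeps maximum number of full sweeps.
#' @param crit_tol relative per-sweep criterion decrease below which the
#'   minimization counts as converged.
#' @return list with orthogonal `V`, `sweeps`, `converged`, and `criterion`
#'   (off-diagonal criterion before sweep 1 and after each sweep). A
#'   non-converged run returns with `converged = FALSE` and a warning.
#' @export
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 200,
                              crit_tol = 1e-4) {
  if (!length(mats)) stop("need at least one matrix")
  n <- nrow(mats[[1]])
  cube <- array(0, dim = c(n, n, length(mats)))
  for (k in seq_along(mats)) {
    M <- as.matrix(mats[[k]])
    if (nrow(M) != n || ncol(M) != n) stop("matrices must share one dimension")
    scale <- max(abs(M), 1e-300)
    if (max(abs(M - t(M))) > 1e-8 * scale)
      stop("matrix ", k, " is not symmetric")
    cube[, , k] <- (M + t(M)) / 2
  }
  res <- joint_diag_cpp(cube, tol, as.integer(max_sweeps), crit_tol)
  if (!res$converged)
    warning("joint diagonalization did not converge in ", max_sweeps,
            " sweeps (last max rotation ", signif(res$last_max_rotation, 3), ")")
  res$criterion <- as.numeric(res$criterion)
  res
}

#' SOBI decomposition of an EEG recording
#'
#' Second-order blind identification: the recording is whitened, its
#' time-lagged covariance matrices at the given delays are jointly
#' diagonalized, and the resulting rotation yields the unmixing matrix `W`
#' and mixing matrix `A` under the instantaneous linear mixing model
#' `x(t) = A s(t)`, `s(t) = W x(t)` (applied to mean-removed data).
#'
#' Scale and sign are fixed by convention: each column of `A` has unit
#' Euclidean norm with its absolutely largest element positive (the inverse
#' scaling is absorbed into the sources), and components are ordered by
#' decreasing source variance.
#'
#' @param rec an [eeg_recording()] (recommended duration at least ten times
#'   the maximum lag).
#' @param lags_ms delays in ms; default [default_lags_ms()].
#' @param tol rotation-angle stopping threshold for [joint_diagonalize()];
#'   the default `NULL` uses the conventional data-scaled threshold
#'   `1 / (100 * sqrt(N))` (floored at 1e-8), below which rotations are
#'   smaller than the sampling noise of the covariance estimates.
#' @param max_sweeps passed to [joint_diagonalize()].
#' @return object of class `sobi_decomposition`: `W` (components x channels),
#'   `A` (channels x components, unit-norm columns), `S` (component time
#'   courses, components x samples), `center` (channel means removed before
#'   unmixing), `labels`, `lags_ms`, `lags_samples`, `rank`, and joint
#'   diagonalization diagnostics `jd` (`sweeps`, `converged`, `criterion`).
#' @export
sobi <- function(rec, lags_ms = default_lags_ms(), tol = NULL, max_sweeps = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  N <- n_samples(rec)
  if (is.null(tol)) tol <- max(1e-8, 1 / (100 * sqrt(N)))
  lags <- lags_to_samples(lags_ms, rec$srate, N)
  if (N < 10 * max(lags))
    warning("record length (", N, ") is below 10x the maximum lag; ",
            "lagged covariance estimates may be unstable")
  wh <- whiten(rec$data)
  R <- lagged_covariances(wh$z, lags, symmetrize = TRUE)
  jd <- joint_diagonalize(R, tol = tol, max_sweeps = max_sweeps)
  U <- jd$V
  W <- t(U) %*% wh$K                       # rank x n
  A <- wh$dewhiten %*% U                   # n x rank; right inverse of W
  # scale/sign convention: unit-norm A columns, largest |element| positive
  nrm <- sqrt(colSums(A^2))
  sgn <- apply(A, 2L, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  A <- sweep(A, 2L, nrm * sgn, "/")
  W <- sweep(W, 1L, nrm * sgn, "*")
  S <- W %*% (rec$data - wh$center)
  ord <- order(rowMeans(S^2) - rowMeans(S)^2, decreasing = TRUE)
  structure(list(W = W[ord, , drop = FALSE], A = A[, ord, drop = FALSE],
                 S = S[ord, , drop = FALSE], center = wh$center,
                 labels = rec$labels, lags_ms = lags_ms, lags_samples = lags,
                 rank = wh$rank,
                 jd = jd[c("sweeps", "converged", "criterion")]),
            class = "sobi_decomposition")
}

#' @export
print.sobi_decomposition <- function(x, ...) {
  cat(sprintf(
    "<sobi_decomposition> %d components from %d channels (%d lags, %d sweeps%s)\n",
    nrow(x$S), length(x$labels), length(x$lags_samples), x$jd$sweeps,
    if (x$jd$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between `P = W %*% A_true` and a
#' scaled permutation matrix; 0 means perfect separation, values below ~0.1
#' indicate good recovery.
#'
#' @param P square matrix (estimated unmixing times true mixing).
#' @return scalar in `[0, 1]`-ish range (normalized by `2 n (n - 1)`).
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  n <- nrow(P)
  if (ncol(P) != n) stop("P must be square")
  rows <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

#' Match estimated components to reference sources
#'
#' Greedy assignment by absolute Pearson correlation of time courses,
#' resolving the permutation/sign indeterminacy of blind source separation.
#'
#' @param S_est estimated components x samples.
#' @param S_ref reference sources x samples (same sample count).
#' @return data.frame with one row per reference source: `ref`, `est`
#'   (matched component index), `abs_cor`.
#' @export
match_components <- function(S_est, S_ref) {
  if (ncol(S_est) != ncol(S_ref)) stop("sample counts differ")
  cc <- abs(cor(t(S_est), t(S_ref)))     # est x ref
  cc[!is.finite(cc)] <- 0
  res <- data.frame(ref = seq_len(ncol(cc)), est = NA_integer_, abs_cor = NA_real_)
  for (i in seq_len(min(dim(cc)))) {
    k <- arrayInd(which.max(cc), dim(cc))
    res$est[k[2]] <- k[1]
    res$abs_cor[k[2]] <- cc[k[1], k[2]]
    cc[k[1], ] <- -1
    cc[, k[2]] <- -1
  }
  res
}
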