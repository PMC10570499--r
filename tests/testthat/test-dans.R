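# Build a minimal synthetic decomposition with known event-locked structure:
# component 1 responds +1 to rightward / -1 to leftward outer targets,
# component 2 +1 up / -1 down; the rest are noise. Scalp projections: the
# two ocular prototypes (plus perturbation) and random smooth maps.
make_fake_decomposition <- function(seed = 20, n_noise = 4) {
  set.seed(seed)
  srate <- 500
  lay <- sensor_layout_64()
  codes <- rep(c("dot_outer_0", "dot_outer_180", "dot_outer_90",
                 "dot_outer_270"), each = 2)
  onsets <- 1000L + seq_along(codes) * 1500L
  N <- max(onsets) + 1000L
  n_comp <- 2L + n_noise
  S <- matrix(rnorm(n_comp * N, sd = 0.05), n_comp, N)
  resp <- function(code) switch(code,
    dot_outer_0 = c(1, 0), dot_outer_180 = c(-1, 0),
    dot_outer_90 = c(0, 1), dot_outer_270 = c(0, -1))
  for (i in seq_along(onsets)) {
    r <- resp(codes[i])
    idx <- onsets[i] + 0:600
    S[1, idx] <- S[1, idx] + r[1]
    S[2, idx] <- S[2, idx] + r[2]
  }
  A <- cbind(prototype_map(lay, "H"), prototype_map(lay, "V"))
  for (j in seq_len(n_noise)) {
    w <- rnorm(64)
    A <- cbind(A, w / sqrt(sum(w^2)))
  }
  events <- data.frame(sample = onsets, code = codes,
                       target_x_mm = 252, target_y_mm = 142.5)
  dec <- structure(list(S = S, A = A, labels = lay$label, srate = srate),
                   class = "sobi_decomposition")
  list(dec = dec, events = events, srate = srate, layout = lay)
}

test_that("SRP amplitude implements baseline-corrected window medians", {
  srate <- 500
  N <- 3000
  onset <- 1500L
  # unit step at onset with flat baseline -> amplitude 1
  step <- c(rep(0, onset - 1), rep(1, N - onset + 1))
  expect_equal(unname(srp_amplitude(step, onset, srate)), 1)
  # a constant source is removed by baseline correction
  expect_equal(unname(srp_amplitude(rep(3.7, N), onset, srate)), 0)
  # ramp source, 2 trials: direct per-sample oracle
  src <- seq_len(N) / N
  onsets <- c(1200L, 1900L)
  rel <- -250:600
  epochs <- sapply(onsets, function(o) src[o + rel])
  avg <- rowMeans(epochs)
  avg <- avg - mean(avg[rel >= -250 & rel < 0])
  expected <- median(avg[rel >= 100 & rel <= 600])
  expect_equal(unname(srp_amplitude(src, onsets, srate)), expected,
               tolerance = 1e-12)
  expect_error(srp_amplitude(src, integer(0), srate), "no trials")
  expect_error(srp_amplitude(src, 100L, srate), "beyond")
})

test_that("single-trial amplitudes agree with per-trial SRP computation", {
  set.seed(21)
  S <- matrix(rnorm(2 * 5000), 2)
  onsets <- c(1000L, 2500L, 4000L)
  M <- single_trial_amplitudes(S, onsets, 500)
  expect_equal(dim(M), c(3L, 2L))
  for (i in 1:3)
    expect_equal(M[i, ], unname(srp_amplitude(S, onsets[i], 500)))
})

test_that("discriminant index normalizes signed differences by the absolute maximum", {
  di <- discriminant_index(c(4, 0, 1), c(0, 2, 0))   # d = (4, -2, 1)
  expect_equal(unname(di), c(1, 0.5, 0.25))
  # direction-insensitive component
  expect_equal(unname(discriminant_index(c(2, 5), c(2, 1))), c(0, 1))
  flat <- discriminant_index(c(1, 1), c(1, 1))
  expect_equal(as.numeric(flat), c(0, 0))
  expect_true(isTRUE(attr(flat, "flat")))
})

test_that("similarity index thresholds normalized correlations at 0.5", {
  lay <- sensor_layout_64()
  proto <- prototype_map(lay, "H")
  set.seed(22)
  noise <- rnorm(64); noise <- noise - mean(noise)
  # residualize the noise direction against the prototype so its
  # correlation is essentially zero
  noise <- noise - proto * sum(noise * (proto - mean(proto))) /
    sum((proto - mean(proto))^2)
  a2 <- 0.37 * (proto - mean(proto)) + sqrt(1 - 0.37^2) * noise / sd(noise) * sd(proto)
  A <- cbind(proto, a2, noise, 0 * noise)
  si <- unname(similarity_index(A, proto))
  expect_equal(si[1], 1)                        # self-similarity
  expect_equal(si[3], 0)                        # orthogonal projection
  expect_equal(si[4], 0)                        # zero-variance projection
  raw2 <- abs(cor(a2, proto))
  expect_equal(si[2], if (raw2 < 0.5) 0 else raw2)
  expect_lt(raw2, 0.5)                          # by construction ~0.37
  expect_error(similarity_index(A[1:10, ], proto), "channel count")
})

test_that("selection takes the largest nonzero scores on distinct components", {
  sc <- data.frame(component = 1:3,
                   DI_H = c(0, 1, 0.2), SI_H = c(0, 0.9, 0.5),
                   H_score = c(0, 0.9, 0.1),
                   DI_V = c(1, 0, 0.4), SI_V = c(0.8, 0, 0.5),
                   V_score = c(0.8, 0, 0.2))
  sel <- dans_select(sc)
  expect_equal(sel, list(h = 2L, v = 1L))
  # shared argmax: larger score keeps the component, other re-selects
  sc2 <- sc
  sc2$H_score <- c(0.9, 0.3, 0)
  sc2$V_score <- c(0.7, 0.1, 0.2)
  expect_equal(dans_select(sc2), list(h = 1L, v = 3L))
  # all-zero axis errors
  sc3 <- sc
  sc3$V_score <- c(0, 0, 0)
  expect_error(dans_select(sc3), "vertical")
})

test_that("DANS scores identify the injected structure and respect BSS indeterminacies", {
  fx <- make_fake_decomposition()
  sc <- dans_scores(fx$dec, fx$events, fx$srate, fx$layout)
  expect_equal(max(sc$DI_H), 1)
  expect_equal(which.max(sc$H_score), 1L)
  expect_equal(which.max(sc$V_score), 2L)
  expect_true(all(sc$SI_H %in% 0 | sc$SI_H >= 0.5))
  sel <- dans_select(sc)
  expect_equal(sel, list(h = 1L, v = 2L))

  # sign flips leave every index unchanged
  dec_f <- fx$dec
  flip <- diag(c(-1, 1, -1, 1, -1, 1))
  dec_f$S <- flip %*% dec_f$S
  dec_f$A <- dec_f$A %*% flip
  sc_f <- dans_scores(dec_f, fx$events, fx$srate, fx$layout)
  expect_equal(sc_f, sc, tolerance = 1e-12)

  # arbitrary rescaling, once the package convention is re-applied
  sc_scale <- diag(exp(runif(6, -2, 2)))
  conv <- apply_bss_convention(sc_scale %*% fx$dec$S,
                               fx$dec$A %*% solve(sc_scale))
  dec_s <- fx$dec
  dec_s$S <- conv$S
  dec_s$A <- conv$A
  sc_s <- dans_scores(dec_s, fx$events, fx$srate, fx$layout)
  expect_equal(sc_s$H_score, sc$H_score, tolerance = 1e-9)
  expect_equal(dans_select(sc_s), sel)

  # permuting components permutes scores and follows the selection
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  dec_p <- fx$dec
  dec_p$S <- dec_p$S[perm, ]
  dec_p$A <- dec_p$A[, perm]
  sc_p <- dans_scores(dec_p, fx$events, fx$srate, fx$layout)
  expect_equal(sc_p$H_score, sc$H_score[perm], tolerance = 1e-12)
  sel_p <- dans_select(sc_p)
  expect_equal(perm[sel_p$h], sel$h)
  expect_equal(perm[sel_p$v], sel$v)
})

test_that("missing condition trials are reported by name", {
  fx <- make_fake_decomposition()
  ev <- fx$events[fx$events$code != "dot_outer_90", ]
  expect_error(dans_scores(fx$dec, ev, fx$srate, fx$layout), "dot_outer_90")
})
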