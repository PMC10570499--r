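# Shared fixtures. The default simulated session and its calibrated model
# are expensive (seconds), so they are built once per test run.

.cache <- new.env(parent = emptyenv())

cached_session <- function() {
  if (is.null(.cache$ses))
    .cache$ses <- simulate_session(simulation_spec(seed = 42))
  .cache$ses
}

cached_model <- function() {
  if (is.null(.cache$model)) {
    s <- cached_session()
    .cache$model <- calibrate(s$rec, s$events, s$geom)
  }
  .cache$model
}

# independent 3-D oracle for angular separation: angle between the two
# eye-to-point vectors, eye on the screen-center normal at viewing distance
angle_3d <- function(p1, p2, geom) {
  ctr <- screen_center(geom)
  v1 <- cbind(p1[, 1] - ctr[1], p1[, 2] - ctr[2], geom$distance)
  v2 <- cbind(p2[, 1] - ctr[1], p2[, 2] - ctr[2], geom$distance)
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

random_points <- function(n, geom) {
  cbind(runif(n, 0, geom$width), runif(n, 0, geom$height))
}

# AR(2) sources with spread resonance peaks (distinct spectra, the SOBI
# identifiability condition)
ar_sources <- function(n_src, N, srate = 500, fmin = 2, fmax = 45) {
  S <- sapply(seq(fmin, fmax, length.out = n_src), function(f) {
    r <- 0.97
    as.numeric(stats::filter(rnorm(N), c(2 * r * cos(2 * pi * f / srate), -r^2),
                             method = "recursive"))
  })
  S <- t(S)
  S / sqrt(rowMeans(S^2))
}

random_orthogonal <- function(n) qr.Q(qr(matrix(rnorm(n * n), n)))

# re-apply the package's scale/sign convention after an indeterminacy
# transform (unit-norm mixing columns, largest element positive)
apply_bss_convention <- function(S, A) {
  nrm <- sqrt(colSums(A^2))
  sgn <- apply(A, 2L, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  list(S = sweep(S, 1L, nrm * sgn, "*"), A = sweep(A, 2L, nrm * sgn, "/"))
}
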