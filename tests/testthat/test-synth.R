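geom <- screen_geometry()

test_that("the dot protocol implements the two-ring, eight-direction design", {
  p <- make_dot_protocol(geom, seed = 3)
  expect_equal(nrow(p), 32L)
  loc <- table(p$code)
  expect_equal(length(loc), 16L)
  expect_true(all(loc == 2L))
  expect_setequal(unique(p$dir_deg), seq(0, 315, by = 45))
  # ring eccentricities map to on-screen mm through the viewing distance
  r <- onscreen_distance(cbind(p$target_x_mm, p$target_y_mm), geom)
  expect_equal(r[p$ring == "outer"], rep(600 * tan(12.2 * pi / 180),
                                         sum(p$ring == "outer")),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r[p$ring == "inner"], rep(600 * tan(6.1 * pi / 180),
                                         sum(p$ring == "inner")),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(p$fix_dur_ms >= 500 & p$fix_dur_ms <= 1000))
  # a direction-0 outer target sits right of center on the horizontal axis
  t0 <- p[p$code == "dot_outer_0", ][1, ]
  expect_equal(t0$target_y_mm, 142.5)
  expect_equal(t0$target_x_mm, 252 + 600 * tan(12.2 * pi / 180))
})

test_that("the pursuit protocol implements the speed-by-direction design", {
  p <- make_pursuit_protocol(geom, seed = 3)
  expect_equal(nrow(p), 64L)
  cells <- table(p$speed_dps, p$dir)
  expect_equal(dim(cells), c(4L, 2L))
  expect_true(all(cells == 8L))
  expect_setequal(unique(p$speed_dps), c(1, 5, 9, 19))
  expect_true(all(p$fix_dur_ms >= 600 & p$fix_dur_ms <= 900))
  # steps sit 23 mm from center, opposite the motion direction
  expect_true(all(p$step_x_mm[p$dir == "left"] == 275))
  expect_true(all(p$step_x_mm[p$dir == "right"] == 229))
  # motion covers speed * 0.512 s of visual angle
  a0 <- atan((p$step_x_mm - 252) / 600) * 180 / pi
  a1 <- atan((p$final_x_mm - 252) / 600) * 180 / pi
  sgn <- ifelse(p$dir == "left", -1, 1)
  expect_equal(a1 - a0, sgn * p$speed_dps * 0.512, tolerance = 1e-9)
})

test_that("protocols and sessions are reproducible from their seed", {
  expect_identical(make_dot_protocol(geom, 5), make_dot_protocol(geom, 5))
  expect_false(identical(make_dot_protocol(geom, 5)$code,
                         make_dot_protocol(geom, 6)$code))
  s1 <- simulate_session(simulation_spec(seed = 9), tasks = "dot")
  s2 <- simulate_session(simulation_spec(seed = 9), tasks = "dot")
  expect_identical(s1$rec$data, s2$rec$data)
  expect_identical(s1$truth$gaze, s2$truth$gaze)
  expect_identical(s1$events, s2$events)
})

test_that("degenerate behavioral settings reproduce the target trajectory", {
  spec0 <- simulation_spec(seed = 4, jitter_deg = 0,
                           saccade_latency_ms = c(mean = 0, sd = 0, min = 0))
  set.seed(4)
  gt <- gaze_from_protocol(make_dot_protocol(geom, 4), geom, spec0)
  # after each saccade lands, gaze sits exactly on the target until offset
  for (i in seq_len(nrow(gt$trials))) {
    tr <- gt$trials[i, ]
    land <- tr$onset + eegvet:::ms2samp(80, 500)
    idx <- (land + 1L):(tr$off - 1L)   # the return saccade may start at off
    expect_equal(gt$gaze$x_mm[idx], rep(tr$target_x, length(idx)),
                 ignore_attr = TRUE)
    expect_equal(gt$gaze$y_mm[idx], rep(tr$target_y, length(idx)),
                 ignore_attr = TRUE)
  }
})

test_that("pursuit lag grows with target speed", {
  spec <- simulation_spec(seed = 5, jitter_deg = 0)
  set.seed(5)
  gt <- gaze_from_protocol(make_pursuit_protocol(geom, 5), geom, spec)
  err_by_speed <- sapply(c(1, 19), function(sp) {
    rows <- gt$trials[gt$trials$speed == sp, ]
    mean(sapply(seq_len(nrow(rows)), function(i) {
      tr <- rows[i, ]
      idx <- tr$move_on:tr$move_end
      sgn <- if (tr$dir == "left") -1 else 1
      a0 <- atan((tr$step_x - 252) / 600) * 180 / pi
      tau <- (idx - tr$move_on) / 500
      targ <- 252 + 600 * tan((a0 + sgn * tr$speed * tau) * pi / 180)
      mean(abs(gt$gaze$x_mm[idx] - targ))
    }))
  })
  expect_gt(err_by_speed[2], err_by_speed[1])
})

test_that("injected ocular sources are affine in the true gaze", {
  ses <- cached_session()
  ctr <- screen_center(ses$geom)
  expect_equal(ses$truth$S[1, ],
               ses$truth$g_h * (ses$truth$gaze$x_mm - ctr[1]),
               tolerance = 1e-12)
  expect_equal(ses$truth$S[2, ],
               ses$truth$g_v * (ses$truth$gaze$y_mm - ctr[2]),
               tolerance = 1e-12)
  # generating coefficients invert the gains
  expect_equal(unname(ses$truth$coef["a_x"]), 1 / ses$truth$g_h)
  expect_equal(unname(ses$truth$coef["c_x"]), ctr[1])
})

test_that("ocular fields project frontally", {
  ses <- cached_session()
  lay <- sensor_layout_64()
  frontal <- which(lay$y > 0.7)
  posterior <- which(lay$y < -0.7)
  cors <- abs(cor(t(ses$rec$data[c(frontal, posterior), ]),
                  ses$truth$gaze$x_mm))
  n_f <- length(frontal)
  expect_gt(mean(cors[seq_len(n_f)]), mean(cors[-seq_len(n_f)]))
})

test_that("background sources keep distinct spectral peaks", {
  set.seed(6)
  bg <- eegvet:::background_sources(20, 20000, 500)
  peaks <- apply(bg, 1, function(s) {
    sp <- stats::spec.pgram(ts(s, frequency = 500), spans = 31, plot = FALSE,
                            taper = 0)
    sp$freq[which.max(sp$spec)]
  })
  # every oscillatory source has its own resonance; only the slow drift
  # and the slowest AR source may share the lowest bin
  expect_gte(length(unique(round(peaks, 1))), 18L)
})

test_that("a written session directory loses nothing", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(seed = 11, srate = 500)
  ses <- simulate_session(spec, tasks = "dot")
  write_session(ses, dir)
  rec <- read_eeg(file.path(dir, "eeg.tsv"))
  expect_equal(rec$data, ses$rec$data, tolerance = 1e-9, ignore_attr = TRUE)
  ev <- read_events(file.path(dir, "events.tsv"))
  expect_equal(ev, ses$events, ignore_attr = TRUE)
  g <- read_geometry(file.path(dir, "geometry.json"))
  expect_equal(g$distance, ses$geom$distance)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$g_h, ses$truth$g_h)
  expect_equal(unlist(truth$coef), ses$truth$coef)
})
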