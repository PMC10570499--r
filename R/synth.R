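# Forward-model simulator: task protocols -> ground-truth gaze -> source
# time courses -> mixed 64-channel EEG. The ocular sources are affine in the
# gaze coordinates by construction, which is exactly the assumption the
# calibration regression relies on, so parameter recovery closes the loop.

#' Simulation settings
#'
#' Collects every tunable of the forward model. Defaults pin the study
#' conditions the rest of the package is tested under: 64 channels at
#' 500 Hz, 20 stationary background sources with distinct spectral peaks,
#' ocular-to-background amplitude ratio 3, and conventional oculomotor
#' behavior (saccade latency ~N(180, 30) ms truncated at 100 ms,
#' amplitude-scaled 40-80 ms minimum-jerk saccades, smooth pursuit with gain
#' 0.9 and 100 ms lag, fixational jitter of 0.1 deg).
#'
#' @param seed RNG seed for the whole session.
#' @param srate sampling rate in Hz.
#' @param n_channels channel count; must match the sensor layout (64).
#' @param n_background number of background (non-ocular) sources.
#' @param ocular_ratio RMS amplitude of each ocular source relative to the
#'   unit-RMS background sources.
#' @param sensor_noise_sd white sensor noise SD (source units, i.e. relative
#'   to unit-RMS background sources).
#' @param mixing_jitter SD of the perturbation applied to the prototypical
#'   ocular scalp maps when building the true mixing columns, as a fraction
#'   of the map norm.
#' @param amp_uv overall output scale in uV.
#' @param saccade_latency_ms mean, SD and truncation floor of saccade
#'   latency, ms.
#' @param saccade_dur_ms_range minimum-jerk saccade duration range, ms
#'   (scaled by amplitude up to the outer-ring eccentricity).
#' @param pursuit_gain,pursuit_lag_ms smooth-pursuit gain and lag.
#' @param jitter_deg fixational jitter SD in degrees (horizontal jitter is
#'   white; vertical jitter is AR(1)-smoothed, mirroring the slower spectral
#'   content of vertical fixational movement).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1, srate = 500, n_channels = 64,
                            n_background = 20, ocular_ratio = 3,
                            sensor_noise_sd = 0.1, mixing_jitter = 0.1,
                            amp_uv = 10,
                            saccade_latency_ms = c(mean = 180, sd = 30, min = 100),
                            saccade_dur_ms_range = c(40, 80),
                            pursuit_gain = 0.9, pursuit_lag_ms = 100,
                            jitter_deg = 0.1) {
  spec <- list(seed = seed, srate = srate, n_channels = n_channels,
               n_background = n_background, ocular_ratio = ocular_ratio,
               sensor_noise_sd = sensor_noise_sd, mixing_jitter = mixing_jitter,
               amp_uv = amp_uv, saccade_latency_ms = saccade_latency_ms,
               saccade_dur_ms_range = saccade_dur_ms_range,
               pursuit_gain = pursuit_gain, pursuit_lag_ms = pursuit_lag_ms,
               jitter_deg = jitter_deg)
  num <- unlist(spec[c("srate", "n_channels", "n_background", "ocular_ratio",
                       "amp_uv")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("simulation settings must be positive")
  structure(spec, class = "simulation_spec")
}

#' Dot-tracking (calibration) protocol
#'
#' 32 directed saccade trials: 16 target locations (8 directions x 2 rings
#' at 6.1 and 12.2 degrees of eccentricity), each visited twice, in a seeded
#' random order. Each trial has a center fixation of random 500-1000 ms,
#' then the target for 1500 ms, then a 600 ms inter-trial gap. Directions
#' are measured counterclockwise from rightward on the viewed screen, so
#' 90 degrees is "up" (decreasing screen Y).
#'
#' @param geom a [screen_geometry()].
#' @param seed RNG seed for trial order and fixation jitter.
#' @return data.frame of class `task_protocol` (one row per trial) with
#'   timing attributes.
#' @export
make_dot_protocol <- function(geom = screen_geometry(), seed = 1) {
  ctr <- screen_center(geom)
  grid <- expand.grid(dir_deg = seq(0, 315, by = 45),
                      ring = c("inner", "outer"), rep = 1:2,
                      stringsAsFactors = FALSE)
  ecc <- c(inner = 6.1, outer = 12.2)
  grid$ecc_deg <- ecc[grid$ring]
  r_mm <- deg_to_mm(grid$ecc_deg, geom)
  grid$target_x_mm <- ctr[1] + r_mm * cos(grid$dir_deg * pi / 180)
  grid$target_y_mm <- ctr[2] - r_mm * sin(grid$dir_deg * pi / 180)
  if (any(grid$target_x_mm < 0 | grid$target_x_mm > geom$width |
          grid$target_y_mm < 0 | grid$target_y_mm > geom$height))
    stop("dot targets fall off screen for this geometry")
  set.seed(seed)
  grid <- grid[sample.int(nrow(grid)), ]
  grid$fix_dur_ms <- runif(nrow(grid), 500, 1000)
  grid$code <- sprintf("dot_%s_%d", grid$ring, grid$dir_deg)
  grid$type <- "dot"
  rownames(grid) <- NULL
  structure(grid, class = c("task_protocol", "data.frame"),
            timing = list(target_ms = 1500, gap_ms = 600), geom = geom)
}

#' Smooth-pursuit (test) protocol
#'
#' 64 trials: 8 per cell of 4 speeds (1, 5, 9, 19 deg/s) x 2 pursuit
#' directions (left, right), seeded random order. Each trial: center
#' fixation of random 600-900 ms, a step target 23 mm (~2.2 deg) to the side
#' opposite the upcoming motion, 256 ms static, 512 ms of motion at the
#' trial's speed, 256 ms static, 600 ms gap.
#'
#' @param geom a [screen_geometry()].
#' @param seed RNG seed.
#' @return data.frame of class `task_protocol` with timing attributes.
#' @export
make_pursuit_protocol <- function(geom = screen_geometry(), seed = 1) {
  ctr <- screen_center(geom)
  step_mm <- 23
  grid <- expand.grid(speed_dps = c(1, 5, 9, 19), dir = c("left", "right"),
                      rep = 1:8, stringsAsFactors = FALSE)
  # the step is opposite the motion direction
  grid$step_x_mm <- ifelse(grid$dir == "left", ctr[1] + step_mm,
                           ctr[1] - step_mm)
  sgn <- ifelse(grid$dir == "left", -1, 1)
  a0 <- atan((grid$step_x_mm - ctr[1]) / geom$distance) * 180 / pi
  a1 <- a0 + sgn * grid$speed_dps * 0.512
  grid$final_x_mm <- ctr[1] + deg_to_mm(a1, geom)
  if (any(grid$final_x_mm < 0 | grid$final_x_mm > geom$width))
    stop("pursuit end points fall off screen for this geometry")
  set.seed(seed)
  grid <- grid[sample.int(nrow(grid)), ]
  grid$fix_dur_ms <- runif(nrow(grid), 600, 900)
  grid$code <- sprintf("%s_%g", grid$dir, grid$speed_dps)
  grid$type <- "pursuit"
  rownames(grid) <- NULL
  structure(grid, class = c("task_protocol", "data.frame"),
            timing = list(step_ms = 256, move_ms = 512, post_ms = 256,
                          gap_ms = 600), geom = geom)
}

ms2samp <- function(ms, srate) as.integer(round(ms * srate / 1000))

# Lay the trials of one or more protocols on a common sample axis.
# Returns the trial table with absolute segment sample indices, the event
# table, and the total sample count (1 s lead-in and tail at center).
protocol_timeline <- function(protocols, srate, geom) {
  if (inherits(protocols, "task_protocol")) protocols <- list(protocols)
  ctr <- screen_center(geom)
  cursor <- srate + 1L                     # 1 s lead-in
  trials <- list(); events <- list()
  for (proto in protocols) {
    tm <- attr(proto, "timing")
    for (i in seq_len(nrow(proto))) {
      tr <- proto[i, ]
      fix_on <- cursor
      onset <- fix_on + ms2samp(tr$fix_dur_ms, srate)
      if (tr$type == "dot") {
        t_off <- onset + ms2samp(tm$target_ms, srate)
        t_end <- t_off + ms2samp(tm$gap_ms, srate)
        trials[[length(trials) + 1L]] <- data.frame(
          type = "dot", code = tr$code, fix_on = fix_on, onset = onset,
          off = t_off, end = t_end,
          target_x = tr$target_x_mm, target_y = tr$target_y_mm,
          ecc_deg = tr$ecc_deg, speed = NA, dir = NA, step_x = NA,
          final_x = NA, move_on = NA, move_end = NA)
        events[[length(events) + 1L]] <- data.frame(
          sample = c(fix_on, onset),
          code = c("fix", tr$code),
          target_x_mm = c(ctr[1], tr$target_x_mm),
          target_y_mm = c(ctr[2], tr$target_y_mm))
        cursor <- t_end
      } else {
        move_on <- onset + ms2samp(tm$step_ms, srate)
        move_end <- move_on + ms2samp(tm$move_ms, srate)
        t_off <- move_end + ms2samp(tm$post_ms, srate)
        t_end <- t_off + ms2samp(tm$gap_ms, srate)
        trials[[length(trials) + 1L]] <- data.frame(
          type = "pursuit", code = tr$code, fix_on = fix_on, onset = onset,
          off = t_off, end = t_end, target_x = tr$step_x_mm, target_y = ctr[2],
          ecc_deg = NA, speed = tr$speed_dps, dir = tr$dir,
          step_x = tr$step_x_mm, final_x = tr$final_x_mm,
          move_on = move_on, move_end = move_end)
        events[[length(events) + 1L]] <- data.frame(
          sample = c(fix_on, onset, move_on, move_end),
          code = c("fix", paste0("step_", tr$code), paste0("move_", tr$code),
                   paste0("stop_", tr$code)),
          target_x_mm = c(ctr[1], tr$step_x_mm, tr$step_x_mm, tr$final_x_mm),
          target_y_mm = rep(ctr[2], 4))
        cursor <- t_end
      }
    }
  }
  list(trials = do.call(rbind, trials), events = do.call(rbind, events),
       n_samples = cursor + srate)        # 1 s tail
}

minjerk <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5

# truncated-normal saccade latency in samples
draw_latency <- function(spec, srate) {
  l <- spec$saccade_latency_ms
  ms2samp(max(l["min"], rnorm(1, l["mean"], l["sd"])), srate)
}

saccade_dur_samp <- function(amp_deg, spec, srate) {
  r <- spec$saccade_dur_ms_range
  ms2samp(r[1] + (r[2] - r[1]) * min(amp_deg / 12.2, 1), srate)
}

# fill x[from:to] with a minimum-jerk movement ending at `to_val`,
# starting from x[from - 1]
fill_saccade <- function(x, from, to, to_val) {
  from <- max(from, 2L); to <- min(to, length(x))
  if (to < from) return(x)
  u <- seq_along(from:to) / length(from:to)
  x[from:to] <- x[from - 1L] + (to_val - x[from - 1L]) * minjerk(u)
  x
}

#' Ground-truth gaze from a task protocol
#'
#' Behavioral forward model: saccades start after a truncated-normal latency
#' and follow a minimum-jerk displacement whose duration scales with
#' amplitude; smooth pursuit follows the target position delayed by the
#' pursuit lag and scaled by the pursuit gain, with a catch-up saccade onto
#' the stopped target; fixation carries jitter. Uses the current RNG state
#' (seed it, or use [simulate_session()] which seeds everything).
#'
#' @param protocols a `task_protocol` or list of them (laid out in order).
#' @param geom a [screen_geometry()].
#' @param spec a [simulation_spec()].
#' @return list: `gaze` (a [gaze_trace()] at `spec$srate`), `trials`
#'   (per-trial segment sample table), `events` (event table),
#'   `n_samples`.
#' @export
gaze_from_protocol <- function(protocols, geom = screen_geometry(),
                               spec = simulation_spec()) {
  tl <- protocol_timeline(protocols, spec$srate, geom)
  srate <- spec$srate
  ctr <- screen_center(geom)
  N <- tl$n_samples
  x <- rep(ctr[1], N); y <- rep(ctr[2], N)
  lag <- ms2samp(spec$pursuit_lag_ms, srate)
  for (i in seq_len(nrow(tl$trials))) {
    tr <- tl$trials[i, ]
    if (tr$type == "dot") {
      s0 <- tr$onset + draw_latency(spec, srate)
      s1 <- s0 + saccade_dur_samp(tr$ecc_deg, spec, srate)
      seg <- min(s1 + 1L, N):tr$off
      x[seg] <- tr$target_x; y[seg] <- tr$target_y
      u <- (s0:s1 - s0) / (s1 - s0)
      x[s0:s1] <- ctr[1] + (tr$target_x - ctr[1]) * minjerk(u)
      y[s0:s1] <- ctr[2] + (tr$target_y - ctr[2]) * minjerk(u)
      # return saccade to center during the gap
      r0 <- tr$off + draw_latency(spec, srate)
      r1 <- r0 + saccade_dur_samp(tr$ecc_deg, spec, srate)
      x <- fill_saccade(x, r0, r1, ctr[1])
      y <- fill_saccade(y, r0, r1, ctr[2])
    } else {
      amp0 <- mm_to_deg(abs(tr$step_x - ctr[1]), geom)
      s0 <- tr$onset + draw_latency(spec, srate)
      s1 <- s0 + saccade_dur_samp(amp0, spec, srate)
      x <- fill_saccade(x, s0, s1, tr$step_x)
      hold_to <- min(tr$move_on + lag, tr$off)
      if (s1 < hold_to) x[(s1 + 1L):hold_to] <- tr$step_x
      # pursuit: delayed, gain-scaled copy of the target angle
      sgn <- if (tr$dir == "left") -1 else 1
      a0 <- atan((tr$step_x - ctr[1]) / geom$distance) * 180 / pi
      seg <- (tr$move_on + lag):min(tr$move_end + lag, tr$off)
      tau <- (seg - tr$move_on - lag) / srate
      a_t <- a0 + sgn * tr$speed * tau
      x[seg] <- ctr[1] + deg_to_mm(a0 + spec$pursuit_gain * (a_t - a0), geom)
      # catch-up saccade onto the stopped target, then hold
      last <- seg[length(seg)]
      if (last < tr$off) x[(last + 1L):tr$off] <- x[last]
      c0 <- last + ms2samp(50, srate)
      c1 <- c0 + saccade_dur_samp(1, spec, srate)
      x <- fill_saccade(x, c0, min(c1, tr$off), tr$final_x)
      if (c1 < tr$off) x[(c1 + 1L):tr$off] <- tr$final_x
      r0 <- tr$off + draw_latency(spec, srate)
      r1 <- r0 + saccade_dur_samp(mm_to_deg(abs(tr$final_x - ctr[1]), geom),
                                  spec, srate)
      x <- fill_saccade(x, r0, r1, ctr[1])
    }
  }
  jit <- deg_to_mm(spec$jitter_deg, geom)
  x <- x + rnorm(N, sd = jit)
  y <- y + as.numeric(stats::filter(rnorm(N, sd = jit * sqrt(1 - 0.9^2)),
                                    0.9, method = "recursive"))
  list(gaze = gaze_trace((seq_len(N) - 1) / srate, x, y),
       trials = tl$trials, events = tl$events, n_samples = N)
}

# stationary background sources with distinct spectral peaks:
# one slow drift, alpha-band oscillators with slowly varying envelopes,
# and AR(2) sources with spread resonance frequencies. Unit RMS each.
background_sources <- function(n, N, srate) {
  n_alpha <- max(0L, min(8L, n - 1L))
  n_ar <- n - 1L - n_alpha
  out <- matrix(0, n, N)
  out[1, ] <- stats::filter(rnorm(N), 0.999, method = "recursive")
  row <- 2L
  if (n_alpha > 0) {
    freqs <- seq(8.5, 12.5, length.out = n_alpha)
    for (f in freqs) {
      env <- stats::filter(rnorm(N), 0.995, method = "recursive")
      env <- exp(0.4 * env / sd(env))
      out[row, ] <- sin(2 * pi * f * seq_len(N) / srate + runif(1, 0, 2 * pi)) * env
      row <- row + 1L
    }
  }
  if (n_ar > 0) {
    freqs <- seq(3, 48, length.out = n_ar)
    for (f in freqs) {
      r <- 0.97
      out[row, ] <- stats::filter(rnorm(N),
                                  c(2 * r * cos(2 * pi * f / srate), -r^2),
                                  method = "recursive")
      row <- row + 1L
    }
  }
  out <- out - rowMeans(out)
  out / sqrt(rowMeans(out^2))
}

# smooth random scalp map (low-order spatial polynomial plus roughness)
random_map <- function(layout) {
  w <- cbind(1, layout$x, layout$y, layout$x * layout$y,
             layout$x^2, layout$y^2) %*% rnorm(6) + 0.3 * rnorm(nrow(layout))
  w <- as.numeric(w)
  w / sqrt(sum(w^2))
}

#' Forward-model EEG from a ground-truth gaze trace
#'
#' Builds the source matrix (two ocular sources affine in the gaze
#' coordinates, scaled to `ocular_ratio` times the unit-RMS background
#' sources; `n_background` stationary background sources), mixes it through
#' a known matrix whose ocular columns are the prototypical ocular maps
#' perturbed by seeded noise, and adds white sensor noise. Uses the current
#' RNG state.
#'
#' @param gt result of [gaze_from_protocol()].
#' @param spec a [simulation_spec()].
#' @param geom a [screen_geometry()].
#' @param layout sensor layout (64 channels).
#' @return list: `rec` (an [eeg_recording()]), `events`, and `truth`
#'   (list: `gaze`, `trials`, `S` true sources, `A` true mixing,
#'   `ocular` = indices of the H/V source rows, `g_h`, `g_v` gains in source
#'   units per mm, and `coef` the generating gaze-model coefficients).
#' @export
simulate_eeg <- function(gt, spec = simulation_spec(),
                         geom = screen_geometry(),
                         layout = sensor_layout_64()) {
  if (spec$n_channels != nrow(layout))
    stop("spec$n_channels must match the sensor layout (", nrow(layout), ")")
  ctr <- screen_center(geom)
  N <- gt$n_samples
  dx <- gt$gaze$x_mm - ctr[1]
  dy <- gt$gaze$y_mm - ctr[2]
  if (sd(dx) == 0 || sd(dy) == 0)
    stop("gaze trace has a constant coordinate; cannot scale ocular sources")
  g_h <- spec$ocular_ratio / sqrt(mean(dx^2))
  g_v <- spec$ocular_ratio / sqrt(mean(dy^2))
  S <- rbind(g_h * dx, g_v * dy,
             background_sources(spec$n_background, N, spec$srate))
  perturb <- function(p) {
    v <- p + rnorm(length(p), sd = spec$mixing_jitter / sqrt(length(p)))
    v / sqrt(sum(v^2))
  }
  A <- cbind(perturb(prototype_map(layout, "H")),
             perturb(prototype_map(layout, "V")))
  for (j in seq_len(spec$n_background)) A <- cbind(A, random_map(layout))
  X <- spec$amp_uv * (A %*% S +
                      matrix(rnorm(spec$n_channels * N,
                                   sd = spec$sensor_noise_sd),
                             spec$n_channels, N))
  rec <- eeg_recording(X, spec$srate, layout$label)
  events <- validate_events(gt$events, n_samples = N, geom = geom)
  truth <- list(gaze = gt$gaze, trials = gt$trials, S = S, A = A,
                ocular = c(h = 1L, v = 2L), g_h = g_h, g_v = g_v,
                coef = c(a_x = 1 / g_h, b_x = 0, c_x = ctr[1],
                         a_y = 0, b_y = 1 / g_v, c_y = ctr[2]))
  list(rec = rec, events = events, truth = truth)
}

#' Simulate a full recording session
#'
#' Generates the dot-tracking (calibration) protocol and, optionally, the
#' smooth-pursuit (test) protocol, synthesizes the ground-truth gaze, and
#' forward-models the EEG, all reproducibly from `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param geom a [screen_geometry()].
#' @param tasks which tasks to include, in session order.
#' @param layout sensor layout.
#' @return object of class `vet_session`: `rec`, `events`, `geom`, `spec`,
#'   `truth`.
#' @export
simulate_session <- function(spec = simulation_spec(),
                             geom = screen_geometry(),
                             tasks = c("dot", "pursuit"),
                             layout = sensor_layout_64()) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  protos <- list()
  if ("dot" %in% tasks)
    protos <- c(protos, list(make_dot_protocol(geom, seed = spec$seed)))
  if ("pursuit" %in% tasks)
    protos <- c(protos, list(make_pursuit_protocol(geom, seed = spec$seed + 1L)))
  set.seed(spec$seed + 2L)
  gt <- gaze_from_protocol(protos, geom, spec)
  sim <- simulate_eeg(gt, spec, geom, layout)
  structure(c(sim, list(geom = geom, spec = spec)), class = "vet_session")
}

#' @export
print.vet_session <- function(x, ...) {
  cat(sprintf("<vet_session> seed %d: %d trials, %d channels x %d samples @ %g Hz\n",
              x$spec$seed, nrow(x$truth$trials), x$rec$n,
              ncol(x$rec$data), x$rec$srate))
  invisible(x)
}

#' Write a simulated session to a directory
#'
#' Writes `eeg.tsv` (+ `.json` sidecar), `events.tsv`, `geometry.json`, and
#' the ground truth (`gaze.tsv`, `truth.json` with the mixing matrix, gains
#' and generating coefficients).
#'
#' @param session a [simulate_session()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_eeg(session$rec, file.path(dir, "eeg.tsv"))
  write_events(session$events, file.path(dir, "events.tsv"))
  write_geometry(session$geom, file.path(dir, "geometry.json"))
  write_gaze(session$truth$gaze, file.path(dir, "gaze.tsv"))
  jsonlite::write_json(
    list(A = session$truth$A, ocular = session$truth$ocular,
         g_h = session$truth$g_h, g_v = session$truth$g_v,
         coef = as.list(session$truth$coef), seed = session$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
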