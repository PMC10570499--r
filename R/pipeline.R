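# Orchestration of the calibration -> tracking -> evaluation flow:
# calibrate() estimates everything individual-specific (unmixing matrix,
# ocular component indices, regression parameters) from a session containing
# the dot-tracking task; track() and evaluate() apply a stored model to
# pursuit trials. Source separation runs once on the continuous recording
# (calibration and test data together when both are in the session).

#' Calibrate an EEG-VET model
#'
#' Runs the full calibration chain on a continuous recording containing the
#' dot-tracking task: pre-filtering, SOBI decomposition, DANS scoring and
#' ocular component selection, single-trial SRP amplitudes, and the gaze
#' regression fit.
#'
#' @param rec an [eeg_recording()] (raw; set `prefilter = FALSE` if already
#'   filtered).
#' @param events event table including dot-task onsets (see [dans_scores()]
#'   for the codes used).
#' @param geom a [screen_geometry()].
#' @param layout sensor layout matching the recording's channel order.
#' @param lags_ms SOBI lag set in ms.
#' @param prefilter apply [preprocess()] first (0.1 Hz high-pass, 50 Hz
#'   notch).
#' @param verbose print per-stage diagnostics.
#' @return object of class `eegvet_model`: `W`, `A`, `center`, `labels`,
#'   `lags_ms`, `selection` (`h`, `v` component indices), `scores` (DANS
#'   table), `fit` (the [gaze_model()][fit_gaze_model()]), `srate`, `jd`
#'   convergence info. Component time courses of the calibration run are in
#'   `S` (not serialized by [write_model()]).
#' @export
calibrate <- function(rec, events, geom = screen_geometry(),
                      layout = sensor_layout_64(),
                      lags_ms = default_lags_ms(), prefilter = TRUE,
                      verbose = FALSE) {
  events <- validate_events(events, n_samples = n_samples(rec), geom = geom)
  if (!any(grepl("^dot_", events$code)))
    stop("calibration needs dot-task events (codes 'dot_*')")
  say <- function(...) if (verbose) message(sprintf(...))
  if (prefilter) {
    t0 <- proc.time()[3]
    rec <- preprocess(rec)
    say("preprocess: %.1f s", proc.time()[3] - t0)
  }
  t0 <- proc.time()[3]
  dec <- sobi(rec, lags_ms = lags_ms)
  say("sobi: %d components, %d sweeps, %.1f s", nrow(dec$S), dec$jd$sweeps,
      proc.time()[3] - t0)
  scores <- dans_scores(dec, events, rec$srate, layout)
  sel <- dans_select(scores)
  say("dans: H = component %d (score %.3f), V = component %d (score %.3f)",
      sel$h, scores$H_score[sel$h], sel$v, scores$V_score[sel$v])
  cal <- calibration_set(dec$S[c(sel$h, sel$v), , drop = FALSE], events,
                         rec$srate)
  fit <- fit_gaze_model(cal)
  say("fit: r_x = %.3f, r_y = %.3f over %d trials", fit$r["r_x"],
      fit$r["r_y"], fit$n_trials)
  structure(list(W = dec$W, A = dec$A, center = dec$center, S = dec$S,
                 labels = dec$labels, lags_ms = lags_ms, selection = sel,
                 scores = scores, calibration = cal, fit = fit,
                 srate = rec$srate, jd = dec$jd),
            class = "eegvet_model")
}

#' @export
print.eegvet_model <- function(x, ...) {
  cat(sprintf("<eegvet_model> %d channels; H comp %d, V comp %d; r_x = %.3f, r_y = %.3f\n",
              ncol(x$W), x$selection$h, x$selection$v,
              x$fit$r["r_x"], x$fit$r["r_y"]))
  invisible(x)
}

# Parse pursuit trials out of an event table: each step_* event with its
# surrounding fix / move_* / stop_* events.
parse_pursuit_trials <- function(events) {
  idx <- grep("^step_", events$code)
  if (!length(idx)) stop("no pursuit trials (codes 'step_*') in event table")
  fix_idx <- which(events$code == "fix")
  out <- lapply(idx, function(i) {
    m <- sub("^step_", "", events$code[i])
    parts <- strsplit(m, "_")[[1]]
    j_move <- which(events$code == paste0("move_", m) & events$sample > events$sample[i])[1]
    j_stop <- which(events$code == paste0("stop_", m) & events$sample > events$sample[i])[1]
    j_fix <- max(fix_idx[events$sample[fix_idx] < events$sample[i]])
    if (is.na(j_move) || is.na(j_stop) || !is.finite(j_fix))
      stop("incomplete pursuit trial around event ", i)
    data.frame(dir = parts[1], speed = as.numeric(parts[2]),
               fix_sample = events$sample[j_fix], step_sample = events$sample[i],
               move_sample = events$sample[j_move],
               stop_sample = events$sample[j_stop],
               step_x = events$target_x_mm[i], step_y = events$target_y_mm[i],
               final_x = events$target_x_mm[j_stop],
               final_y = events$target_y_mm[j_stop])
  })
  do.call(rbind, out)
}

# Extract the stored H/V component time courses from a recording
model_sources <- function(model, rec, prefilter = TRUE) {
  if (!identical(model$labels, rec$labels))
    stop("channel labels of the recording do not match the model (",
         ncol(model$W), " channels expected)")
  if (prefilter) rec <- preprocess(rec)
  W_hv <- model$W[c(model$selection$h, model$selection$v), , drop = FALSE]
  W_hv %*% (rec$data - rowMeans(rec$data))
}

#' Track gaze through the pursuit trials of a session
#'
#' Applies the stored unmixing matrix, extracts the selected H/V component
#' time courses, and predicts per-sample gaze for each pursuit trial, using
#' the trial's fixation-cross interval as amplitude baseline. The trial
#' window runs from step-target onset to 256 ms past motion end.
#'
#' @param model an `eegvet_model` (from [calibrate()] or [read_model()]).
#' @param rec the session recording (raw by default).
#' @param events the session event table.
#' @param smooth_ms moving-average width for [track_gaze()].
#' @param prefilter apply [preprocess()] before unmixing.
#' @return list of class `vet_tracking`: `trials` (parsed pursuit trial
#'   table), `traces` (list of per-trial [gaze_trace()]s), `srate`.
#' @export
track <- function(model, rec, events, smooth_ms = 25, prefilter = TRUE) {
  stopifnot(inherits(model, "eegvet_model"))
  S_hv <- model_sources(model, rec, prefilter = prefilter)
  trials <- parse_pursuit_trials(events)
  post <- ms2samp(256, model$srate)
  traces <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    track_gaze(model$fit, S_hv, model$srate,
               trial_window = c(tr$step_sample, min(tr$stop_sample + post,
                                                    ncol(S_hv))),
               baseline_window = c(tr$fix_sample, tr$step_sample - 1L),
               smooth_ms = smooth_ms)
  })
  structure(list(trials = trials, traces = traces, srate = model$srate),
            class = "vet_tracking")
}

# target trajectory of one pursuit trial on the trial's sample grid
target_trajectory <- function(tr, srate, geom) {
  ctr <- screen_center(geom)
  post <- ms2samp(256, srate)
  samp <- tr$step_sample:(tr$stop_sample + post)
  x <- rep(tr$step_x, length(samp))
  sgn <- if (tr$dir == "left") -1 else 1
  a0 <- atan((tr$step_x - ctr[1]) / geom$distance) * 180 / pi
  moving <- samp >= tr$move_sample & samp <= tr$stop_sample
  tau <- (samp[moving] - tr$move_sample) / srate
  x[moving] <- ctr[1] + deg_to_mm(a0 + sgn * tr$speed * tau, geom)
  x[samp > tr$stop_sample] <- tr$final_x
  gaze_trace((samp - 1) / srate, x, rep(tr$step_y, length(samp)))
}

#' Evaluate tracking performance on a pursuit session
#'
#' Computes the saccade-test accuracy and precision (on the fixation
#' interval 200-256 ms after each step-target onset, one measured position
#' per trial) and the per-trial pursuit trajectory RMSE on a common
#' `n_points` grid, aggregated by speed x direction cell.
#'
#' @param model an `eegvet_model`.
#' @param rec,events the session recording and event table.
#' @param geom a [screen_geometry()].
#' @param n_points trajectory grid size per trial.
#' @param prefilter apply [preprocess()] before unmixing.
#' @return list of class `vet_report`: `accuracy_deg`, `precision_deg`,
#'   `saccade` (per-trial table), `rmse` (per speed x direction cell:
#'   `rmse_x_mm`, `rmse_y_mm`, `n`), `rmse_trials` (per-trial values).
#' @export
evaluate <- function(model, rec, events, geom = screen_geometry(),
                     n_points = 180, prefilter = TRUE) {
  trk <- track(model, rec, events, prefilter = prefilter)
  srate <- trk$srate
  w0 <- ms2samp(200, srate); w1 <- ms2samp(256, srate)
  sacc <- lapply(seq_len(nrow(trk$trials)), function(i) {
    tr <- trk$trials[i, ]
    trace <- trk$traces[[i]]
    rel <- round(trace$t_s * srate + 1) - tr$step_sample
    win <- rel >= w0 & rel <= w1
    pts <- cbind(trace$x_mm[win], trace$y_mm[win])
    data.frame(dir = tr$dir, speed = tr$speed,
               target_x = tr$step_x, target_y = tr$step_y,
               meas_x = mean(pts[, 1]), meas_y = mean(pts[, 2]),
               precision_deg = gaze_precision(pts, geom))
  })
  sacc <- do.call(rbind, sacc)
  acc <- gaze_accuracy(cbind(sacc$target_x, sacc$target_y),
                       cbind(sacc$meas_x, sacc$meas_y), geom)
  sacc$accuracy_deg <- acc$per_trial_deg
  rmse_tr <- lapply(seq_len(nrow(trk$trials)), function(i) {
    tr <- trk$trials[i, ]
    pred <- resample_trace(trk$traces[[i]], n_points)
    targ <- resample_trace(target_trajectory(tr, srate, geom), n_points)
    e <- pursuit_rmse(pred, targ)
    data.frame(dir = tr$dir, speed = tr$speed,
               rmse_x_mm = e["rmse_x"], rmse_y_mm = e["rmse_y"])
  })
  rmse_tr <- do.call(rbind, rmse_tr)
  rownames(rmse_tr) <- NULL
  agg <- stats::aggregate(cbind(rmse_x_mm, rmse_y_mm) ~ speed + dir,
                          data = rmse_tr, FUN = mean)
  agg$n <- stats::aggregate(rmse_x_mm ~ speed + dir, data = rmse_tr,
                            FUN = length)$rmse_x_mm
  agg <- agg[order(agg$dir, agg$speed), ]
  rownames(agg) <- NULL
  structure(list(accuracy_deg = acc$mean_deg,
                 precision_deg = mean(sacc$precision_deg),
                 saccade = sacc, rmse = agg, rmse_trials = rmse_tr),
            class = "vet_report")
}

#' @export
print.vet_report <- function(x, ...) {
  cat(sprintf("<vet_report> accuracy %.3f deg, precision %.3f deg over %d saccade trials\n",
              x$accuracy_deg, x$precision_deg, nrow(x$saccade)))
  cat("pursuit RMSE (mm) by speed x direction:\n")
  print(x$rmse, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' JSON (full report) plus a TSV of the per-cell RMSE table next to it.
#'
#' @param report a [evaluate()] result.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(accuracy_deg = report$accuracy_deg,
         precision_deg = report$precision_deg,
         rmse = report$rmse, saccade = report$saccade),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  data.table::fwrite(report$rmse, sub("\\.json$", "_rmse.tsv", path),
                     sep = "\t")
  invisible(path)
}
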