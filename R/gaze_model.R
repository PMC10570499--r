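# The gaze mapping is a pair of affine equations fitted per individual:
#   X_t = a_x * Amp_H + b_x * Amp_V + c_x
#   Y_t = a_y * Amp_H + b_y * Amp_V + c_y
# where Amp_H / Amp_V are single-trial SRP amplitudes of the selected ocular
# components (arbitrary source units; the regression absorbs the scale left
# free by source separation) and targets are screen coordinates in mm.

#' Build a calibration set from dot-task trials
#'
#' Computes single-trial SRP amplitudes of the selected H and V components at
#' every dot-task target onset (event codes starting with `dot_`), paired
#' with the known target coordinates.
#'
#' @param S_hv 2 x samples matrix: H component time course in row 1, V in
#'   row 2.
#' @param events event table; rows with codes matching `^dot_` are used.
#' @param srate sampling rate (Hz).
#' @param window,baseline SRP windows in ms (see [srp_amplitude()]).
#' @return data.frame of class `calibration_set`: `code`, `amp_h`, `amp_v`,
#'   `target_x_mm`, `target_y_mm`.
#' @export
calibration_set <- function(S_hv, events, srate, window = c(200, 1200),
                            baseline = c(-500, 0)) {
  if (nrow(S_hv) != 2L) stop("S_hv must have exactly two rows (H, V)")
  dot <- events[grepl("^dot_", events$code), , drop = FALSE]
  if (!nrow(dot)) stop("no dot-task trials (codes 'dot_*') in the event table")
  amps <- single_trial_amplitudes(S_hv, dot$sample, srate, window, baseline)
  out <- data.frame(code = dot$code, amp_h = amps[, 1], amp_v = amps[, 2],
                    target_x_mm = dot$target_x_mm,
                    target_y_mm = dot$target_y_mm)
  class(out) <- c("calibration_set", "data.frame")
  out
}

#' Fit the individual gaze model
#'
#' Ordinary least squares of target X and Y coordinates on the H and V
#' component amplitudes (with intercept). Reports the six parameters, the
#' multiple correlation coefficient per axis, and two-sided t-test p-values
#' per predictor (n - 3 degrees of freedom) as fit diagnostics.
#'
#' @param cal a [calibration_set()] (or any data.frame with columns `amp_h`,
#'   `amp_v`, `target_x_mm`, `target_y_mm`); needs >= 3 trials spanning a
#'   full-rank design.
#' @return object of class `gaze_model` with elements `coef` (named vector
#'   `a_x, b_x, c_x, a_y, b_y, c_y`), `r` (named `r_x`, `r_y`), `p` (2 x 2
#'   matrix of per-predictor p-values), `n_trials`.
#' @export
fit_gaze_model <- function(cal) {
  need <- c("amp_h", "amp_v", "target_x_mm", "target_y_mm")
  stopifnot(all(need %in% names(cal)))
  X <- cbind(1, cal$amp_h, cal$amp_v)
  if (nrow(X) < 3L || qr(X)$rank < 3L)
    stop("calibration design is rank deficient; provide at least 3 trials ",
         "with non-collinear amplitude spread")
  fx <- lm(target_x_mm ~ amp_h + amp_v, data = cal)
  fy <- lm(target_y_mm ~ amp_h + amp_v, data = cal)
  cx <- coef(fx); cy <- coef(fy)
  # summary.lm warns on exact affine data ("essentially perfect fit");
  # noiseless calibration is a supported case here
  sx <- suppressWarnings(summary(fx))
  sy <- suppressWarnings(summary(fy))
  px <- sx$coefficients[c("amp_h", "amp_v"), 4]
  py <- sy$coefficients[c("amp_h", "amp_v"), 4]
  structure(list(
    coef = c(a_x = unname(cx["amp_h"]), b_x = unname(cx["amp_v"]),
             c_x = unname(cx["(Intercept)"]),
             a_y = unname(cy["amp_h"]), b_y = unname(cy["amp_v"]),
             c_y = unname(cy["(Intercept)"])),
    r = c(r_x = sqrt(sx$r.squared), r_y = sqrt(sy$r.squared)),
    p = rbind(x = px, y = py),
    n_trials = nrow(cal)),
    class = "gaze_model")
}

#' @export
print.gaze_model <- function(x, ...) {
  cat(sprintf("<gaze_model> %d calibration trials; r_x = %.3f, r_y = %.3f\n",
              x$n_trials, x$r["r_x"], x$r["r_y"]))
  cat(sprintf("  X = %+.4g*AmpH %+.4g*AmpV %+.4g\n",
              x$coef["a_x"], x$coef["b_x"], x$coef["c_x"]))
  cat(sprintf("  Y = %+.4g*AmpH %+.4g*AmpV %+.4g\n",
              x$coef["a_y"], x$coef["b_y"], x$coef["c_y"]))
  invisible(x)
}

#' Predict an on-screen gaze point
#'
#' Affine evaluation of the two fitted gaze equations. Vectorized over
#' amplitudes.
#'
#' @param model a [fit_gaze_model()] result.
#' @param amp_h,amp_v component amplitudes (source units).
#' @return matrix with columns `x_mm`, `y_mm`.
#' @export
predict_gaze_point <- function(model, amp_h, amp_v) {
  stopifnot(inherits(model, "gaze_model"))
  k <- model$coef
  cbind(x_mm = k["a_x"] * amp_h + k["b_x"] * amp_v + k["c_x"],
        y_mm = k["a_y"] * amp_h + k["b_y"] * amp_v + k["c_y"],
        deparse.level = 0)
}

# centered moving average with edge replication
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  xp <- c(rep(x[1], k %/% 2), x, rep(x[length(x)], k - 1 - k %/% 2))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[
    (k %/% 2 + 1):(k %/% 2 + length(x))]
}

#' Continuous gaze tracking over a trial
#'
#' Maps per-sample, baseline-corrected H/V component amplitudes through the
#' fitted gaze equations. The baseline is the mean component level over the
#' trial's pre-target fixation window, so each trial's prediction starts at
#' the model intercepts (the screen center seen during fixation). A short
#' moving average (default 25 ms) suppresses sample-to-sample noise; the
#' trace can optionally be resampled to an evaluation rate.
#'
#' @param model a [fit_gaze_model()] result.
#' @param S_hv 2 x samples matrix (H, V component time courses).
#' @param srate sampling rate (Hz).
#' @param trial_window integer `c(from, to)` sample range to predict.
#' @param baseline_window integer `c(from, to)` sample range of the preceding
#'   fixation interval (non-empty).
#' @param smooth_ms moving-average width in ms (0 disables).
#' @param resample_hz optional output rate; `NULL` keeps the EEG rate.
#' @return a [gaze_trace()] with absolute timestamps in s.
#' @export
track_gaze <- function(model, S_hv, srate, trial_window, baseline_window,
                       smooth_ms = 25, resample_hz = NULL) {
  stopifnot(nrow(S_hv) == 2L)
  if (baseline_window[2] < baseline_window[1])
    stop("baseline window is empty")
  tw <- trial_window[1]:trial_window[2]
  bw <- baseline_window[1]:baseline_window[2]
  if (min(bw, tw) < 1L || max(bw, tw) > ncol(S_hv))
    stop("trial or baseline window outside the recording")
  k <- max(1L, as.integer(round(smooth_ms * srate / 1000)))
  sm <- rbind(moving_average(S_hv[1, ], k), moving_average(S_hv[2, ], k))
  amp_h <- sm[1, tw] - mean(sm[1, bw])
  amp_v <- sm[2, tw] - mean(sm[2, bw])
  p <- predict_gaze_point(model, amp_h, amp_v)
  tr <- gaze_trace((tw - 1) / srate, p[, "x_mm"], p[, "y_mm"])
  if (!is.null(resample_hz)) {
    tt <- seq(tr$t_s[1], tr$t_s[nrow(tr)], by = 1 / resample_hz)
    tr <- gaze_trace(tt,
                     stats::approx(tr$t_s, tr$x_mm, tt)$y,
                     stats::approx(tr$t_s, tr$y_mm, tt)$y)
  }
  tr
}

#' Serialize / load a fitted EEG-VET model
#'
#' The model file is JSON holding the unmixing and mixing matrices
#' (row-major), channel labels, lag set, selected component indices, the six
#' regression parameters with fit diagnostics, and the DANS scores table.
#'
#' @param model an `eegvet_model` as returned by [calibrate()].
#' @param path destination JSON path.
#' @return `write_model`: `path` invisibly; `read_model`: an `eegvet_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "eegvet_model"))
  obj <- list(
    labels = model$labels, lags_ms = model$lags_ms,
    W = as.vector(t(model$W)), A = as.vector(t(model$A)),
    n_components = nrow(model$W), n_channels = ncol(model$W),
    center = model$center,
    h_component = model$selection$h, v_component = model$selection$v,
    coef = as.list(model$fit$coef),
    r = as.list(model$fit$r),
    p = list(x = as.list(model$fit$p["x", ]), y = as.list(model$fit$p["y", ])),
    n_trials = model$fit$n_trials,
    scores = as.data.frame(model$scores),
    srate = model$srate,
    jd = model$jd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- structure(list(coef = unlist(o$coef), r = unlist(o$r),
                        p = rbind(x = unlist(o$p$x), y = unlist(o$p$y)),
                        n_trials = o$n_trials),
                   class = "gaze_model")
  structure(list(
    W = matrix(o$W, o$n_components, o$n_channels, byrow = TRUE),
    A = matrix(o$A, o$n_channels, o$n_components, byrow = TRUE),
    center = o$center, labels = o$labels, lags_ms = o$lags_ms,
    selection = list(h = o$h_component, v = o$v_component),
    scores = o$scores, fit = fit, srate = o$srate, jd = o$jd),
    class = "eegvet_model")
}
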