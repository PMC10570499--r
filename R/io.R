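#' EEG recording container
#'
#' Bundles a channels-by-samples amplitude matrix (microvolts) with its
#' sampling rate and channel labels. This is the multichannel time series
#' \eqn{x(t)} that blind source separation decomposes: each channel is an
#' instantaneous linear mixture of underlying sources.
#'
#' @param data numeric matrix, channels in rows, samples in columns, in uV.
#' @param srate sampling rate in Hz (scalar, > 0).
#' @param labels character vector of unique channel names, one per row.
#'   Defaults to `ch01`, `ch02`, ...
#' @return An object of class `eeg_recording` with elements `data`, `srate`,
#'   `labels`, `n` (channel count).
#' @export
eeg_recording <- function(data, srate, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("an EEG recording needs at least 2 channels")
  if (!is.numeric(srate) || length(srate) != 1L || !is.finite(srate) || srate <= 0)
    stop("'srate' must be a single positive number (Hz)")
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("number of labels (", length(labels), ") does not match channel count (",
         nrow(data), ")")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite samples in channel(s): ", paste(labels[bad], collapse = ", "))
  rownames(data) <- labels
  structure(list(data = data, srate = as.numeric(srate), labels = labels,
                 n = nrow(data)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$n, ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an [eeg_recording()].
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read an EEG recording (plain-matrix dialect)
#'
#' Reads the package's on-disk EEG dialect: a whitespace-separated numeric
#' matrix (channels in rows, samples in columns, microvolts) accompanied by a
#' JSON sidecar holding `srate` (Hz), `labels`, and optionally `units`
#' (must be `"uV"` when present; no silent rescaling is ever performed).
#'
#' @param path path to the matrix file (TSV).
#' @param sidecar path to the JSON sidecar; default `paste0(path, ".json")`.
#' @param format_hint optional format name. Only `"matrix"` is supported;
#'   binary formats (EDF/BDF/FIF) are rejected with an informative error.
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, sidecar = paste0(path, ".json"), format_hint = "matrix") {
  if (!identical(format_hint, "matrix"))
    stop("unsupported EEG format '", format_hint,
         "'; this build reads the plain-matrix + JSON sidecar dialect only")
  if (!file.exists(path)) stop("EEG matrix file not found: ", path)
  if (!file.exists(sidecar)) stop("EEG sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$srate)) stop("sidecar missing 'srate': ", sidecar)
  if (!is.null(meta$units) && !identical(toupper(meta$units), "UV"))
    stop("EEG units must be uV, got '", meta$units, "' (no silent rescaling)")
  x <- as.matrix(data.table::fread(path, header = FALSE))
  if (!is.null(meta$labels) && length(meta$labels) != nrow(x))
    stop("sidecar declares ", length(meta$labels), " labels but matrix has ",
         nrow(x), " rows")
  eeg_recording(x, srate = meta$srate, labels = meta$labels)
}

#' Write an EEG recording (plain-matrix dialect)
#'
#' @param rec an [eeg_recording()].
#' @param path destination matrix file; the JSON sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  data.table::fwrite(data.table::as.data.table(rec$data), path, sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(list(srate = rec$srate, labels = rec$labels, units = "uV"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Screen geometry
#'
#' Viewing geometry used by every visual-angle computation: screen width and
#' height in mm and the eye-to-screen distance in mm. The eye is assumed to
#' lie on the normal through the screen center. Coordinates on screen use the
#' upper-left corner as origin, X rightward and Y downward, in mm.
#'
#' @param width,height screen size in mm.
#' @param distance viewing distance in mm.
#' @return object of class `screen_geometry`.
#' @export
screen_geometry <- function(width = 504, height = 285, distance = 600) {
  vals <- c(width = width, height = height, distance = distance)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("screen geometry values must all be strictly positive")
  structure(list(width = width, height = height, distance = distance),
            class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g mm at %g mm viewing distance\n",
              x$width, x$height, x$distance))
  invisible(x)
}

#' Screen center in mm
#' @param geom a [screen_geometry()].
#' @return numeric length-2 vector `(x, y)` in mm.
#' @export
screen_center <- function(geom) c(geom$width / 2, geom$height / 2)

#' Read screen geometry from JSON or YAML
#'
#' Expects fields `width_mm`, `height_mm`, `distance_mm`.
#' @param path file path (`.json`, `.yaml`, `.yml`).
#' @return a [screen_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  g <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("width_mm", "height_mm", "distance_mm")
  if (!all(need %in% names(g)))
    stop("geometry file must define ", paste(need, collapse = ", "))
  screen_geometry(g$width_mm, g$height_mm, g$distance_mm)
}

#' Write screen geometry
#' @param geom a [screen_geometry()].
#' @param path destination (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  g <- list(width_mm = geom$width, height_mm = geom$height,
            distance_mm = geom$distance)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(g, path)
  else jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an event table
#'
#' Events are TSV rows `sample  code  target_x_mm  target_y_mm`: sample index
#' (1-based, strictly increasing), a string code tagging the trial phase and
#' condition, and the on-screen target coordinates in mm at that event.
#'
#' @param path TSV file with header.
#' @param n_samples optional recording length for bounds checking.
#' @param geom optional [screen_geometry()]; when given, coordinates are
#'   required to lie on the screen.
#' @return a `data.frame` with columns `sample`, `code`, `target_x_mm`,
#'   `target_y_mm`.
#' @export
read_events <- function(path, n_samples = NULL, geom = NULL) {
  if (!file.exists(path)) stop("event file not found: ", path)
  ev <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_events(ev, n_samples = n_samples, geom = geom)
}

#' Validate an event table
#' @inheritParams read_events
#' @param events data.frame of events.
#' @return the validated `data.frame` (invisibly usable).
#' @export
validate_events <- function(events, n_samples = NULL, geom = NULL) {
  need <- c("sample", "code", "target_x_mm", "target_y_mm")
  if (!all(need %in% names(events)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  events <- events[, need]
  events$sample <- as.integer(events$sample)
  if (any(events$sample < 1L)) stop("event sample indices must be >= 1")
  if (is.unsorted(events$sample, strictly = TRUE))
    stop("event sample indices must be strictly increasing")
  if (!is.null(n_samples) && any(events$sample > n_samples))
    stop("event sample index beyond recording length (", n_samples, ")")
  if (!is.null(geom)) {
    bad <- events$target_x_mm < 0 | events$target_x_mm > geom$width |
           events$target_y_mm < 0 | events$target_y_mm > geom$height
    if (any(bad)) stop("event target coordinates outside screen bounds (rows ",
                       paste(which(bad), collapse = ", "), ")")
  }
  events
}

#' Write an event table
#' @param events data.frame with columns `sample`, `code`, `target_x_mm`,
#'   `target_y_mm`.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' Gaze trace container
#'
#' Timestamps in seconds and screen coordinates in mm (origin upper-left,
#' X rightward, Y downward).
#' @param t numeric timestamps (s), non-decreasing.
#' @param x,y coordinates in mm.
#' @return object of class `gaze_trace` (a data.frame with columns
#'   `t_s`, `x_mm`, `y_mm`).
#' @export
gaze_trace <- function(t, x, y) {
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have equal length")
  if (is.unsorted(t)) stop("gaze timestamps must be non-decreasing")
  structure(data.frame(t_s = t, x_mm = x, y_mm = y),
            class = c("gaze_trace", "data.frame"))
}

#' Write / read a gaze trace as TSV
#' @param trace a [gaze_trace()].
#' @param path TSV path with header `t_s  x_mm  y_mm`.
#' @return `write_gaze`: `path` invisibly; `read_gaze`: a [gaze_trace()].
#' @export
write_gaze <- function(trace, path) {
  stopifnot(all(c("t_s", "x_mm", "y_mm") %in% names(trace)))
  data.table::fwrite(as.data.frame(trace)[, c("t_s", "x_mm", "y_mm")], path,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  g <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("t_s", "x_mm", "y_mm")
  if (!all(need %in% names(g)))
    stop("gaze file must have columns ", paste(need, collapse = ", "))
  gaze_trace(g$t_s, g$x_mm, g$y_mm)
}
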