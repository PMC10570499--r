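# Filtering runs zero-phase (forward-backward) so that saccade-locked epochs
# keep their latency; a causal filter would shift the SRP window.

# Order-4 Butterworth high-pass as two true second-order sections.
# The transfer-function form of a 0.1 Hz / 500 Hz design is numerically
# fragile (poles crowd z = 1), so the analog prototype pair is bilinear-
# transformed section by section. Section damping factors for order 4:
# zeta = cos(pi/8), cos(3*pi/8).
butter_highpass_sos <- function(fc, fs, order = 4) {
  if (order != 4) stop("only the order-4 design is provided")
  wa <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cutoff (rad/s)
  K <- 2 * fs
  lapply(cos(c(pi / 8, 3 * pi / 8)), function(zeta) {
    q <- 1 / (2 * zeta)
    a0 <- K^2 + wa * K / q + wa^2
    list(b = c(K^2, -2 * K^2, K^2) / a0,
         a = c(a0, 2 * (wa^2 - K^2), K^2 - wa * K / q + wa^2) / a0)
  })
}

# RBJ biquad notch.
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  list(b = c(1, -2 * cos(w0), 1) / a0,
       a = c(a0, -2 * cos(w0), 1 - alpha) / a0)
}

# Zero-phase biquad cascade (forward and time-reversed pass per section) in
# compiled code, with reflective end padding long enough for the slow
# high-pass transient. `x` may be a vector or a channels x samples matrix.
apply_filtfilt <- function(x, sections, pad = 4000L) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else t(x)
  B <- sapply(sections, `[[`, "b")
  A <- sapply(sections, `[[`, "a")
  out <- sos_filtfilt_cpp(X, B, A, as.integer(pad))
  if (vec) out[, 1] else t(out)
}

#' Pre-filter an EEG recording
#'
#' Standard continuous-EEG conditioning before source separation: a zero-phase
#' high-pass (default 0.1 Hz, order-4 Butterworth applied as cascaded biquad
#' sections) to remove drift, and a zero-phase notch (default 50 Hz, Q = 30)
#' to remove mains interference.
#'
#' @param rec an [eeg_recording()].
#' @param highpass_hz high-pass cutoff in Hz; `NULL` disables.
#' @param notch_hz notch center frequency in Hz; `NULL` disables.
#' @param notch_q notch quality factor.
#' Channel means are removed before filtering (the DC level of an EEG
#' channel is reference-dependent and meaningless; removing it first keeps
#' the high-pass edge transient small relative to the padding).
#'
#' @return a filtered [eeg_recording()] of identical shape.
#' @export
preprocess <- function(rec, highpass_hz = 0.1, notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  for (f in c(highpass_hz, notch_hz))
    if (!is.null(f) && (f <= 0 || f >= nyq))
      stop("filter frequency ", f, " Hz outside (0, Nyquist = ", nyq, ")")
  if (!is.null(highpass_hz) && !is.null(notch_hz) && highpass_hz >= notch_hz)
    stop("high-pass cutoff must lie below the notch frequency")
  sections <- list()
  if (!is.null(highpass_hz))
    sections <- c(sections, butter_highpass_sos(highpass_hz, rec$srate))
  if (!is.null(notch_hz))
    sections <- c(sections, list(notch_biquad(notch_hz, rec$srate, notch_q)))
  eeg_recording(apply_filtfilt(rec$data - rowMeans(rec$data), sections),
                rec$srate, rec$labels)
}
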