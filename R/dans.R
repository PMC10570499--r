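# DANS: each SOBI component is scored on two axes. The discriminant index
# (DI) asks whether the component's saccade-related potential (SRP) responds
# with opposite sign to long saccades in opposite directions; the similarity
# index (SI) asks whether its scalp projection resembles the prototypical
# ocular topography. The product DI * SI selects the horizontal and vertical
# ocular components. Both indices are invariant to the sign and positive
# rescaling left free by blind source separation.

epoch_offsets <- function(srate, from_ms, to_ms) {
  seq(as.integer(round(from_ms * srate / 1000)),
      as.integer(round(to_ms * srate / 1000)))
}

#' Saccade-related potential amplitude
#'
#' Epochs component time courses around target onsets, averages the epochs,
#' subtracts the mean of the baseline window, and returns the median of the
#' averaged, baseline-corrected response within the measurement window.
#' Defaults: measurement 200-1200 ms after onset, baseline the 500 ms before
#' onset. The value is signed.
#'
#' @param S components x samples matrix (or a single time course).
#' @param onsets integer sample indices of target onsets (>= 1 trial).
#' @param srate sampling rate (Hz).
#' @param window measurement window in ms relative to onset.
#' @param baseline baseline window in ms relative to onset (right-open).
#' @return numeric vector, one signed amplitude per component.
#' @export
srp_amplitude <- function(S, onsets, srate, window = c(200, 1200),
                          baseline = c(-500, 0)) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  if (!length(onsets)) stop("no trials supplied for SRP amplitude")
  rel <- epoch_offsets(srate, baseline[1], window[2])
  if (min(onsets) + rel[1] < 1L || max(onsets) + rel[length(rel)] > ncol(S))
    stop("epoch window [", baseline[1], ", ", window[2],
         "] ms extends beyond the recording for some trial")
  # average epoch per component: comps x reltime
  avg <- 0
  for (o in onsets) avg <- avg + S[, o + rel, drop = FALSE]
  avg <- avg / length(onsets)
  bl_idx <- rel >= as.integer(round(baseline[1] * srate / 1000)) &
            rel < as.integer(round(baseline[2] * srate / 1000))
  win_idx <- rel >= as.integer(round(window[1] * srate / 1000)) &
             rel <= as.integer(round(window[2] * srate / 1000))
  if (!any(bl_idx)) stop("empty baseline window")
  avg <- avg - rowMeans(avg[, bl_idx, drop = FALSE])
  apply(avg[, win_idx, drop = FALSE], 1L, median)
}

#' Single-trial SRP amplitudes
#'
#' Per-trial version of [srp_amplitude()]: one baseline-corrected median per
#' (trial, component), used to build the calibration set for the gaze
#' regression.
#'
#' @inheritParams srp_amplitude
#' @return matrix, trials x components.
#' @export
single_trial_amplitudes <- function(S, onsets, srate, window = c(200, 1200),
                                    baseline = c(-500, 0)) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  out <- matrix(NA_real_, length(onsets), nrow(S))
  for (i in seq_along(onsets))
    out[i, ] <- srp_amplitude(S, onsets[i], srate, window, baseline)
  out
}

#' Discriminant index
#'
#' Normalized difference between the signed SRP amplitudes evoked by long
#' saccades in opposite directions: `d_i = amp_pos_i - amp_neg_i`,
#' `DI_i = |d_i| / max_j |d_j|`. The maximum DI is 1.0 by construction; the
#' absolute value makes the index invariant to the component sign left free
#' by source separation. If every difference is zero, all DI are 0 and the
#' result carries `attr(, "flat") = TRUE`.
#'
#' @param amp_pos,amp_neg per-component signed SRP amplitudes for the two
#'   opposite directions (right/left for H, up/down for V).
#' @return numeric DI in `[0, 1]` per component.
#' @export
discriminant_index <- function(amp_pos, amp_neg) {
  d <- abs(amp_pos - amp_neg)
  m <- max(d)
  if (m == 0) return(structure(rep(0, length(d)), flat = TRUE))
  d / m
}

#' Similarity index
#'
#' Normalized absolute Pearson correlation, over channels, between each
#' component's scalp projection (column of the mixing matrix) and a
#' prototypical ocular map: `SI_i = |r_i| / max_j |r_j|`, then values below
#' 0.5 are set exactly to 0, excluding weakly matching components from
#' selection. Zero-variance projections get SI 0.
#'
#' @param A channels x components mixing matrix (channel order must match the
#'   prototype).
#' @param prototype channel weight vector from [prototype_map()].
#' @return numeric SI per component, each in `{0} U [0.5, 1]`.
#' @export
similarity_index <- function(A, prototype) {
  if (nrow(A) != length(prototype))
    stop("mixing matrix and prototype differ in channel count")
  r <- apply(A, 2L, function(a) if (sd(a) == 0) 0 else abs(cor(a, prototype)))
  m <- max(r)
  if (m == 0) return(rep(0, ncol(A)))
  si <- r / m
  si[si < 0.5] <- 0
  si
}

#' DANS component scores
#'
#' Computes, for every SOBI component, the horizontal and vertical
#' discriminant indices (from outer-ring saccade trials in the four cardinal
#' directions), the similarity indices against the prototypical ocular maps,
#' and the H and V scores (DI x SI).
#'
#' Outer-ring dot-task onsets are located by event code:
#' `dot_outer_0` (right), `dot_outer_180` (left), `dot_outer_90` (up),
#' `dot_outer_270` (down).
#'
#' @param dec a [sobi()] decomposition.
#' @param events event table (see [read_events()]).
#' @param srate sampling rate (Hz).
#' @param layout sensor layout matching the decomposition's channel order.
#' @return data.frame of class `dans_scores`: `component`, `DI_H`, `SI_H`,
#'   `H_score`, `DI_V`, `SI_V`, `V_score`.
#' @export
dans_scores <- function(dec, events, srate, layout = sensor_layout_64()) {
  stopifnot(inherits(dec, "sobi_decomposition"))
  if (!identical(dec$labels, layout$label))
    stop("decomposition channel order does not match the sensor layout")
  cond_onsets <- function(code) {
    s <- events$sample[events$code == code]
    if (!length(s)) stop("no trials with event code '", code, "'")
    s
  }
  amp <- sapply(c(right = "dot_outer_0", left = "dot_outer_180",
                  up = "dot_outer_90", down = "dot_outer_270"),
                function(cd) srp_amplitude(dec$S, cond_onsets(cd), srate))
  di_h <- discriminant_index(amp[, "right"], amp[, "left"])
  di_v <- discriminant_index(amp[, "up"], amp[, "down"])
  si_h <- similarity_index(dec$A, prototype_map(layout, "H"))
  si_v <- similarity_index(dec$A, prototype_map(layout, "V"))
  out <- data.frame(component = seq_len(nrow(dec$S)),
                    DI_H = as.numeric(di_h), SI_H = si_h,
                    H_score = as.numeric(di_h) * si_h,
                    DI_V = as.numeric(di_v), SI_V = si_v,
                    V_score = as.numeric(di_v) * si_v)
  class(out) <- c("dans_scores", "data.frame")
  out
}

#' Select the ocular components
#'
#' Picks the component with the largest nonzero H score and the one with the
#' largest nonzero V score. The two selections must differ: on a tie for the
#' same component, the axis with the larger score keeps it and the other axis
#' re-selects from the remaining components. Ties within an axis break toward
#' the lower component index.
#'
#' @param scores a [dans_scores()] table.
#' @return list with integer `h` and `v` component indices.
#' @export
dans_select <- function(scores) {
  pick <- function(s, exclude = integer()) {
    s[exclude] <- 0
    if (all(s <= 0)) return(NA_integer_)
    which.max(s)                           # which.max takes the first maximum
  }
  h <- pick(scores$H_score)
  v <- pick(scores$V_score)
  if (is.na(h)) stop("no ocular component found for the horizontal axis ",
                     "(all H scores zero)")
  if (is.na(v)) stop("no ocular component found for the vertical axis ",
                     "(all V scores zero)")
  if (h == v) {
    if (scores$H_score[h] >= scores$V_score[v]) {
      v <- pick(scores$V_score, exclude = h)
      if (is.na(v)) stop("no ocular component found for the vertical axis ",
                         "after resolving a shared selection")
    } else {
      h <- pick(scores$H_score, exclude = v)
      if (is.na(h)) stop("no ocular component found for the horizontal axis ",
                         "after resolving a shared selection")
    }
  }
  list(h = as.integer(h), v = as.integer(v))
}

#' Write a DANS scores table as TSV
#' @param scores a [dans_scores()] table.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  data.table::fwrite(as.data.frame(scores), path, sep = "\t")
  invisible(path)
}
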