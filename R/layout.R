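# 2-D head-top-view electrode positions (unitless, nose up: +y anterior,
# +x right) for a standard 64-channel 10-10 montage with mastoids.
# Positions are schematic ring coordinates; they only need to encode the
# left/right and anterior/posterior structure that the prototype scalp maps
# are built from.

row_defs <- list(
  Fp = list(y = 0.95, labels = c("Fp1", "Fpz", "Fp2"), frac = c(-0.35, 0, 0.35)),
  AF = list(y = 0.75, labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
            frac = c(-0.9, -0.38, 0, 0.38, 0.9)),
  F  = list(y = 0.55,
            labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
            frac = c(-0.9, -0.64, -0.38, -0.13, 0, 0.13, 0.38, 0.64, 0.9)),
  FC = list(y = 0.28,
            labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
            frac = c(-1, -0.64, -0.38, -0.13, 0, 0.13, 0.38, 0.64, 1)),
  C  = list(y = 0,
            labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
            frac = c(-1, -0.64, -0.38, -0.13, 0, 0.13, 0.38, 0.64, 1)),
  CP = list(y = -0.28,
            labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
            frac = c(-1, -0.64, -0.38, -0.13, 0, 0.13, 0.38, 0.64, 1)),
  P  = list(y = -0.55,
            labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
            frac = c(-0.9, -0.64, -0.38, -0.13, 0, 0.13, 0.38, 0.64, 0.9)),
  PO = list(y = -0.75, labels = c("PO7", "PO3", "POz", "PO4", "PO8"),
            frac = c(-0.9, -0.38, 0, 0.38, 0.9)),
  O  = list(y = -0.95, labels = c("O1", "Oz", "O2"), frac = c(-0.35, 0, 0.35))
)

#' Standard 64-channel sensor layout
#'
#' Schematic 2-D positions (head-top view, nose up, +x toward the right ear)
#' for a 64-channel 10-10 montage including mastoids (M1/M2) and Iz. Used to
#' build the prototypical ocular scalp maps and to evaluate topographic
#' similarity.
#'
#' @return data.frame with columns `label`, `x`, `y` (64 rows).
#' @export
sensor_layout_64 <- function() {
  rows <- lapply(row_defs, function(r) {
    hw <- sqrt(max(1 - r$y^2, 0.12))     # half-width of the head outline
    data.frame(label = r$labels, x = r$frac * hw, y = r$y)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out,
               data.frame(label = c("M1", "M2", "Iz"),
                          x = c(-1.05, 1.05, 0), y = c(-0.1, -0.1, -1.05)))
  rownames(out) <- NULL
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$label))
  out
}

#' Prototypical ocular scalp maps
#'
#' Analytic templates of the scalp projection of the horizontal and vertical
#' ocular components on a 2-D sensor layout. The horizontal template is a
#' left/right antisymmetric field peaking at the frontal periocular
#' positions (eyes rotating toward one ear produce opposite-polarity fields
#' over the two frontolateral regions); the vertical template is a
#' frontal-maximal field decaying toward posterior sites. Both are
#' unit-normalized.
#'
#' @param layout a layout data.frame as from [sensor_layout_64()].
#' @param axis `"H"` or `"V"`.
#' @return named numeric vector of channel weights (unit Euclidean norm),
#'   names = channel labels.
#' @export
prototype_map <- function(layout = sensor_layout_64(), axis = c("H", "V")) {
  axis <- match.arg(axis)
  w <- if (axis == "H") {
    layout$x * exp(-((layout$y - 0.9)^2) / (2 * 0.4^2))
  } else {
    exp(-(layout$x^2 + (layout$y - 1.1)^2) / (2 * 0.55^2))
  }
  w <- w / sqrt(sum(w^2))
  names(w) <- layout$label
  w
}
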