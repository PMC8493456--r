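#' Annotated training sample
#'
#' One MRC patch triplet plus the organ label mask of its main slice.
#' `selective` samples exist only at physician-chosen key slices; `full`
#' samples exist at every slice intersecting an organ.
#'
#' @param triplet a [extract_patch_triplet()] result (MRC patches).
#' @param label a [segmentation_mask()] for the main slice (same patch size).
#' @param annotation_mode `"selective"` or `"full"`.
#' @return An object of class `annotated_sample`.
#' @export
annotated_sample <- function(triplet, label,
                             annotation_mode = c("selective", "full")) {
  annotation_mode <- match.arg(annotation_mode)
  if (!identical(dim(label$labels), dim(triplet$main)))
    abort_inearseg("label shape differs from patch shape",
                   "inearseg_shape_error")
  structure(list(triplet = triplet, label = label,
                 annotation_mode = annotation_mode),
            class = "annotated_sample")
}

#' Randomly augment an annotated sample
#'
#' Augmentation mirrors the training-time scheme: with probability
#' `flip_probability` the three patches and the label are mirrored left-right
#' together; the crop window is shifted by independent integer row/column
#' offsets drawn from `[-shift_range_px, shift_range_px]`, applied identically
#' to images and label (pixels shifted in from outside are zero-filled); image
#' intensities are scaled by a gain drawn uniformly from
#' `intensity_gain_range` (the label is untouched). Randomness comes from R's
#' RNG, so a fixed `set.seed()` gives a reproducible augmented stream. Each
#' draw can be overridden with an explicit value, which makes the operators
#' easy to test.
#'
#' @param sample an [annotated_sample()].
#' @param flip_probability probability of a horizontal mirror.
#' @param shift_range_px maximum absolute shift in pixels.
#' @param intensity_gain_range length-2 numeric, uniform gain bounds.
#' @param flip,shift,gain optional explicit overrides (logical; integer
#'   length-2 `c(drow, dcol)`; numeric scalar).
#' @return An augmented [annotated_sample()].
#' @export
augment_sample <- function(sample, flip_probability = 0.5,
                           shift_range_px = 5L,
                           intensity_gain_range = c(0.8, 1.2),
                           flip = NULL, shift = NULL, gain = NULL) {
  if (is.null(flip)) flip <- runif(1) < flip_probability
  if (is.null(shift))
    shift <- sample.int(2L * shift_range_px + 1L, 2L, replace = TRUE) -
      shift_range_px - 1L
  if (is.null(gain))
    gain <- runif(1, intensity_gain_range[1], intensity_gain_range[2])
  tr <- sample$triplet
  lab <- sample$label$labels
  op <- function(m, is_label = FALSE) {
    if (flip) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m <- shift_matrix(m, shift[1], shift[2])
    if (!is_label) m <- m * gain
    m
  }
  tr$prev <- op(tr$prev); tr$main <- op(tr$main); tr$nxt <- op(tr$nxt)
  out <- sample
  out$triplet <- tr
  out$label$labels <- matrix(as.integer(op(lab, is_label = TRUE)), nrow(lab))
  out
}

# integer translation with zero fill; equivalent to re-cropping at a shifted
# reference point away from the patch border
shift_matrix <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rdst <- rs + dr; cdst <- cs + dc
  ok_r <- rdst >= 1L & rdst <= nrow(m)
  ok_c <- cdst >= 1L & cdst <= ncol(m)
  out[rdst[ok_r], cdst[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}
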