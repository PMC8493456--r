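#' Compose the HYDROPS volume (voxel-wise PPI - PEI)
#'
#' The endolymphatic space carries a stronger positive-endolymph than
#' positive-perilymph signal, so it comes out negative in the difference
#' image. Accepts [volume_stack()]s (returns a `HYDROPS` stack) or bare
#' numeric arrays (returns an array), which is convenient for small numeric
#' checks.
#'
#' @param ppi,pei positive perilymph / endolymph volumes of identical shape.
#' @return The voxel-wise difference, same container type as the input.
#' @export
compute_hydrops <- function(ppi, pei) {
  a <- stack_data(ppi); b <- stack_data(pei)
  check_aligned(a, b)
  out <- a - b
  if (inherits(ppi, "volume_stack"))
    volume_stack(out, "HYDROPS", ppi$voxel_spacing, ppi$subject_id)
  else out
}

#' Compose the HYDROPS-Mi2 volume (voxel-wise HYDROPS x MRC)
#'
#' Multiplying by the heavily T2-weighted cisternography image boosts the
#' contrast-to-noise ratio inside fluid spaces; where MRC is strictly
#' positive the sign of HYDROPS is preserved.
#'
#' @param hydrops,mrc volumes of identical shape.
#' @return The voxel-wise product, same container type as the input.
#' @export
compute_hydrops_mi2 <- function(hydrops, mrc) {
  a <- stack_data(hydrops); b <- stack_data(mrc)
  check_aligned(a, b)
  out <- a * b
  if (inherits(hydrops, "volume_stack"))
    volume_stack(out, "HYDROPS_MI2", hydrops$voxel_spacing,
                 hydrops$subject_id)
  else out
}

stack_data <- function(x) if (inherits(x, "volume_stack")) x$data else x

check_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    abort_inearseg(
      sprintf("shape mismatch: %s vs %s",
              paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
      "inearseg_alignment_error")
  invisible(TRUE)
}

#' Crop a patch around a reference point
#'
#' The reference point lands at patch index (49, 49) (0-based): the crop spans
#' rows `ref.row - 49 .. ref.row + 50` and the analogous columns. Regions
#' falling outside the image are zero-filled with a warning, so reference
#' points near the border never abort a run.
#'
#' @param slice numeric matrix (one image slice).
#' @param row,col 0-based reference pixel.
#' @param size patch side length (default 100).
#' @return `size x size` numeric matrix.
#' @export
crop_patch <- function(slice, row, col, size = PATCH_SIZE) {
  half <- size %/% 2L - 1L                     # 49 for size 100
  r0 <- row - half; c0 <- col - half           # 0-based top-left
  out <- matrix(0, size, size)
  rr <- max(0L, r0):min(nrow(slice) - 1L, r0 + size - 1L)
  cc <- max(0L, c0):min(ncol(slice) - 1L, c0 + size - 1L)
  if (length(rr) < size || length(cc) < size)
    warning("patch extends outside the image; zero-filled", call. = FALSE)
  out[rr - r0 + 1L, cc - c0 + 1L] <- slice[rr + 1L, cc + 1L]
  out
}

#' Extract three consecutive patches around a reference point
#'
#' Crops the previous, main and next slice at the same reference point; this
#' triplet is the network's input unit.
#'
#' @param stack a [volume_stack()].
#' @param ref a [ref_point()].
#' @param main_slice 0-based main slice index, in `[1, N - 2]`.
#' @param size patch side length (default 100).
#' @return An object of class `patch_triplet` with fields `prev`, `main`,
#'   `nxt`, `side`, `main_slice_index`, `subject_id`, `ref`.
#' @export
extract_patch_triplet <- function(stack, ref, main_slice, size = PATCH_SIZE) {
  N <- n_slices(stack)
  main_slice <- as.integer(main_slice)
  if (main_slice < 1L || main_slice > N - 2L)
    abort_inearseg(
      sprintf("main slice %d at stack boundary (valid range 1..%d)",
              main_slice, N - 2L),
      "inearseg_boundary_error")
  p <- lapply(main_slice + (-1:1), function(i)
    crop_patch(stack$data[, , i + 1L], ref$row, ref$col, size))
  structure(list(prev = p[[1]], main = p[[2]], nxt = p[[3]],
                 side = ref$side, main_slice_index = main_slice,
                 subject_id = stack$subject_id,
                 ref = c(row = ref$row, col = ref$col)),
            class = "patch_triplet")
}
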