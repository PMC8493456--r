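#' @name volume_stack
#' @title Single-modality MR volume stack
#'
#' @description
#' A `volume_stack` holds one modality's 3D image as a `rows x cols x slices`
#' numeric array plus a modality tag and voxel geometry. Intensities are always
#' stored as doubles so that HYDROPS subtraction can go negative without
#' integer wrap-around. Slice, row and column indices are 0-based throughout
#' the package; only written reports use 1-based slice numbers.
#'
#' @param data numeric 3D array, `H x W x N_slices` (rows, columns, slices).
#' @param modality one of `"MRC"`, `"PPI"`, `"PEI"`, `"HYDROPS"`,
#'   `"HYDROPS_MI2"`.
#' @param voxel_spacing numeric length-3 vector, mm per voxel edge.
#' @param subject_id subject identifier string.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, modality, voxel_spacing = c(1, 1, 1),
                         subject_id = "") {
  modality <- match.arg(modality, MODALITIES)
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_inearseg("data must be a 3D array (rows x cols x slices)",
                   "inearseg_shape_error")
  if (!all(is.finite(data)))
    abort_inearseg("volume contains non-finite intensities",
                   "inearseg_shape_error")
  d <- dim(data)
  if (d[3] < 3L)
    abort_inearseg(sprintf("stack too short: %d slices, need >= 3", d[3]),
                   "inearseg_stack_error")
  if (d[1] < PATCH_SIZE || d[2] < PATCH_SIZE)
    abort_inearseg(sprintf("in-plane size %dx%d smaller than patch size %d",
                           d[1], d[2], PATCH_SIZE),
                   "inearseg_shape_error")
  structure(list(data = data * 1.0, modality = modality,
                 voxel_spacing = as.numeric(voxel_spacing),
                 subject_id = subject_id),
            class = "volume_stack")
}

MODALITIES <- c("MRC", "PPI", "PEI", "HYDROPS", "HYDROPS_MI2")
PATCH_SIZE <- 100L

#' Number of slices in a volume stack
#' @param x a [volume_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(x) {
  dim(if (inherits(x, "volume_stack")) x$data else x)[3]
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> %s  %dx%d px, %d slices  subject '%s'\n",
              x$modality, d[1], d[2], d[3], x$subject_id))
  invisible(x)
}

#' Reference point for one ear
#'
#' The pixel around which 100x100 patches are cropped. Coordinates are 0-based
#' (row, col). Exactly one reference point per side is expected per study; the
#' package never detects them -- they come from the phantom generator or from a
#' sidecar file in clinical use.
#'
#' @param side `"left"` or `"right"`.
#' @param row,col 0-based pixel indices.
#' @return An object of class `ref_point`.
#' @export
ref_point <- function(side, row, col) {
  side <- match.arg(side, c("left", "right"))
  row <- as.integer(row); col <- as.integer(col)
  if (row < 0L || col < 0L)
    abort_inearseg("reference point indices must be >= 0",
                   "inearseg_parameter_error")
  structure(list(side = side, row = row, col = col), class = "ref_point")
}

#' A subject's aligned multi-modality study
#'
#' Bundles the three aligned modality stacks with the two reference points and
#' (optionally) ground-truth organ masks and key slices. All stacks must share
#' one shape; no resampling is ever performed.
#'
#' @param subject_id subject identifier.
#' @param mrc,ppi,pei [volume_stack()]s of the matching modality.
#' @param ref_points list with elements `left` and `right`, each a
#'   [ref_point()].
#' @param gt_masks optional integer label array of the stack shape with values
#'   0 = background, 1 = left cochlea, 2 = left vestibule, 3 = right cochlea,
#'   4 = right vestibule.
#' @param gt_key_slices optional named integer vector (0-based slice indices)
#'   with names among the four organ classes.
#' @return An object of class `study_case`.
#' @export
study_case <- function(subject_id, mrc, ppi, pei, ref_points,
                       gt_masks = NULL, gt_key_slices = NULL) {
  for (v in list(mrc, ppi, pei))
    if (!inherits(v, "volume_stack"))
      abort_inearseg("mrc, ppi, pei must be volume_stack objects",
                     "inearseg_shape_error")
  if (!identical(dim(mrc$data), dim(ppi$data)) ||
      !identical(dim(mrc$data), dim(pei$data)))
    abort_inearseg("modality stacks are not aligned: shapes differ",
                   "inearseg_alignment_error")
  if (is.null(ref_points$left) || is.null(ref_points$right))
    abort_inearseg("need one reference point per side",
                   "inearseg_parameter_error")
  d <- dim(mrc$data)
  for (rp in ref_points[c("left", "right")])
    if (rp$row >= d[1] || rp$col >= d[2])
      abort_inearseg("reference point outside the image",
                     "inearseg_parameter_error")
  if (!is.null(gt_masks)) {
    if (!identical(dim(gt_masks), d))
      abort_inearseg("gt_masks shape differs from the modality stacks",
                     "inearseg_alignment_error")
    for (cls in seq_along(ORGAN_CLASSES))
      if (!any(gt_masks == cls))
        abort_inearseg(sprintf("ground-truth class '%s' has no pixels",
                               ORGAN_CLASSES[cls]),
                       "inearseg_parameter_error")
  }
  structure(list(subject_id = subject_id, mrc = mrc, ppi = ppi, pei = pei,
                 ref_points = ref_points, gt_masks = gt_masks,
                 gt_key_slices = gt_key_slices),
            class = "study_case")
}

ORGAN_CLASSES <- c("left_cochlea", "left_vestibule",
                   "right_cochlea", "right_vestibule")
organ_side  <- function(organ) ifelse(grepl("^left", organ), "left", "right")
organ_label <- function(organ) ifelse(grepl("cochlea$", organ), 1L, 2L)

#' @export
print.study_case <- function(x, ...) {
  d <- dim(x$mrc$data)
  cat(sprintf(
    "<study_case> '%s'  %dx%d px, %d slices  gt: %s\n",
    x$subject_id, d[1], d[2], d[3],
    if (is.null(x$gt_masks)) "none" else "masks + key slices"))
  invisible(x)
}

#' Per-side, per-slice segmentation labels
#'
#' @param labels integer matrix with values 0 = background, 1 = cochlea,
#'   2 = vestibule.
#' @param side `"left"` or `"right"`.
#' @param slice_index 0-based index of the (main) slice the mask belongs to.
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels, side, slice_index) {
  side <- match.arg(side, c("left", "right"))
  labels <- as.matrix(labels)
  if (!all(labels %in% 0:2))
    abort_inearseg("mask labels must be in {0, 1, 2}", "inearseg_shape_error")
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 side = side, slice_index = as.integer(slice_index)),
            class = "segmentation_mask")
}

#' Load an aligned multi-modality study from NIfTI files
#'
#' Reads the three modality volumes, verifies that they share one shape, and
#' attaches the reference points. Volumes are taken as co-registered; no
#' resampling is performed. Supported input is NIfTI (`.nii` / `.nii.gz`).
#'
#' @param paths named list or vector with elements `mrc`, `ppi`, `pei`, each a
#'   NIfTI file path.
#' @param ref_points either a list with `left`/`right` [ref_point()]s, or the
#'   path of a sidecar JSON file `{"left": [row, col], "right": [row, col]}`
#'   (0-based).
#' @param subject_id subject identifier; defaults to the MRC file stem.
#' @return A [study_case()].
#' @export
load_study <- function(paths, ref_points, subject_id = NULL) {
  paths <- as.list(paths)
  for (m in c("mrc", "ppi", "pei"))
    if (is.null(paths[[m]]) || !file.exists(paths[[m]]))
      abort_inearseg(sprintf("missing or unreadable %s volume", toupper(m)),
                     "inearseg_parameter_error")
  if (is.character(ref_points)) ref_points <- read_ref_points(ref_points)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(paths$mrc))
  read1 <- function(path, mod) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    sp <- RNifti::pixdim(img)
    volume_stack(arr, mod, voxel_spacing = sp[seq_len(min(3, length(sp)))],
                 subject_id = subject_id)
  }
  mrc <- read1(paths$mrc, "MRC")
  ppi <- read1(paths$ppi, "PPI")
  pei <- read1(paths$pei, "PEI")
  study_case(subject_id, mrc, ppi, pei, ref_points)
}

#' Write a volume stack as NIfTI
#'
#' @param x a [volume_stack()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data, pixdim = x$voxel_spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a study (modalities, masks, reference points) to a directory
#'
#' Emits `mrc.nii.gz`, `ppi.nii.gz`, `pei.nii.gz`, optionally
#' `gt_masks.nii.gz`, and `ref_points.json`.
#'
#' @param study a [study_case()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(study$mrc, file.path(dir, "mrc.nii.gz"))
  write_volume(study$ppi, file.path(dir, "ppi.nii.gz"))
  write_volume(study$pei, file.path(dir, "pei.nii.gz"))
  if (!is.null(study$gt_masks))
    RNifti::writeNifti(RNifti::asNifti(study$gt_masks),
                       file.path(dir, "gt_masks.nii.gz"))
  rp <- study$ref_points
  jsonlite::write_json(
    list(left = c(rp$left$row, rp$left$col),
         right = c(rp$right$row, rp$right$col)),
    file.path(dir, "ref_points.json"), auto_unbox = FALSE)
  invisible(dir)
}

read_ref_points <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(left = ref_point("left", j$left[1], j$left[2]),
       right = ref_point("right", j$right[1], j$right[2]))
}

#' Load a study previously written by [write_study()]
#'
#' @param dir study directory.
#' @return A [study_case()].
#' @export
read_study <- function(dir) {
  load_study(list(mrc = file.path(dir, "mrc.nii.gz"),
                  ppi = file.path(dir, "ppi.nii.gz"),
                  pei = file.path(dir, "pei.nii.gz")),
             ref_points = file.path(dir, "ref_points.json"),
             subject_id = basename(dir))
}

#' Remove the mean intensity of a patch
#'
#' Subtracts the arithmetic mean so the result averages zero; applied to every
#' patch before it enters the network (with per-batch normalisation handled by
#' the training loop's intensity conventions).
#'
#' @param patch numeric matrix or array.
#' @return Same shape, zero-mean.
#' @export
mean_subtract <- function(patch) {
  if (!all(is.finite(patch)))
    abort_inearseg("patch contains non-finite values", "inearseg_shape_error")
  patch - mean(patch)
}
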