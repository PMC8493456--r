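#' Per-organ area-vs-slice profile with key-slice selection
#'
#' Holds the segmented pixel count per main slice for one organ class and the
#' selected key slice (the slice with the largest segmented area, smallest
#' index on ties). Main slices are indexed `1 .. N-2` (0-based) because the
#' sliding three-slice window cannot centre on the first or last slice.
#'
#' @param organ_class one of `"left_cochlea"`, `"left_vestibule"`,
#'   `"right_cochlea"`, `"right_vestibule"`.
#' @param areas integer vector of length `N - 2`: segmented pixels per main
#'   slice, in main-slice order.
#' @param N total slice count of the stack.
#' @return An object of class `class_area_profile` with fields `key_index`
#'   (0-based slice index or `NA` if the organ was not detected), `key_area`
#'   and `detected`.
#' @export
class_area_profile <- function(organ_class, areas, N) {
  organ_class <- match.arg(organ_class, ORGAN_CLASSES)
  if (length(areas) == 0L)
    abort_inearseg("empty area series", "inearseg_profile_error")
  if (length(areas) != N - 2L)
    abort_inearseg("area series must have N - 2 entries",
                   "inearseg_profile_error")
  if (any(areas < 0))
    abort_inearseg("areas must be >= 0", "inearseg_profile_error")
  sel <- select_key_slice(areas)
  structure(list(organ_class = organ_class,
                 areas = as.integer(areas), N = as.integer(N),
                 key_index = if (sel$detected) sel$position else NA_integer_,
                 key_area = sel$area, detected = sel$detected),
            class = "class_area_profile")
}

#' Select the representative key slice from an area series
#'
#' The key slice is the main slice with the largest segmented area; ties are
#' broken to the smallest index so the choice is deterministic. An all-zero
#' series means the organ was not detected: no key slice is returned.
#'
#' @param areas integer vector of per-main-slice segmented areas (position
#'   `p` holds main slice `p`, 0-based), or a [class_area_profile()].
#' @return list with `detected` (logical), `position` (0-based main-slice
#'   index, `NA` when not detected) and `area` (pixels at the key slice).
#' @export
select_key_slice <- function(areas) {
  if (inherits(areas, "class_area_profile")) areas <- areas$areas
  if (length(areas) == 0L)
    abort_inearseg("empty area series", "inearseg_profile_error")
  if (all(areas == 0))
    return(list(detected = FALSE, position = NA_integer_, area = 0L))
  p <- which.max(areas)                     # which.max takes the first max
  list(detected = TRUE, position = as.integer(p), area = areas[p])
}

#' Segment a full MRC stack with a sliding three-slice window
#'
#' For each side and each main slice `i` in `1 .. N-2` (0-based), the
#' previous/main/next patches at that side's reference point are fed to the
#' segmenter, yielding exactly `N - 2` masks per side. Per-organ area
#' profiles are accumulated from the mask label counts.
#'
#' @param model a segmenter ([build_network()], [train_curriculum()] or
#'   [gt_oracle_segmenter()]).
#' @param mrc the MRC [volume_stack()].
#' @param refs list with `left` and `right` [ref_point()]s.
#' @return list with `masks` (per side, a list of `N - 2`
#'   [segmentation_mask()]s) and `profiles` (named list of four
#'   [class_area_profile()]s).
#' @export
segment_stack <- function(model, mrc, refs) {
  N <- n_slices(mrc)
  if (N < 3L)
    abort_inearseg("stack too short: need at least 3 slices",
                   "inearseg_stack_error")
  main_idx <- seq.int(1L, N - 2L)
  masks <- list()
  areas <- matrix(0L, nrow = length(main_idx), ncol = 4,
                  dimnames = list(NULL, ORGAN_CLASSES))
  for (side in c("left", "right")) {
    ms <- vector("list", length(main_idx))
    for (k in seq_along(main_idx)) {
      tr <- extract_patch_triplet(mrc, refs[[side]], main_idx[k])
      m <- predict_patch(model, tr)
      ms[[k]] <- m
      areas[k, paste0(side, "_cochlea")]   <- sum(m$labels == 1L)
      areas[k, paste0(side, "_vestibule")] <- sum(m$labels == 2L)
    }
    masks[[side]] <- ms
  }
  profiles <- lapply(ORGAN_CLASSES, function(org)
    class_area_profile(org, areas[, org], N))
  names(profiles) <- ORGAN_CLASSES
  list(masks = masks, profiles = profiles)
}

#' EH ratio of one segmented organ at one slice
#'
#' The endolymphatic hydrops ratio is the fraction of segmented pixels whose
#' HYDROPS-Mi2 value is strictly negative (a value of exactly 0 counts as
#' non-negative). With no segmented pixels the ratio is undefined and
#' reported as `NA` ("not detected"), never as an error.
#'
#' @param mask logical/0-1 matrix selecting the organ's pixels, or a
#'   [segmentation_mask()] together with `organ_label`.
#' @param hydrops_mi2_slice numeric matrix of the same shape (HYDROPS-Mi2
#'   patch or slice).
#' @param organ_label when `mask` is a [segmentation_mask()]: 1 = cochlea,
#'   2 = vestibule.
#' @return An object of class `eh_result`: `p_seg`, `p_neg`, `ratio`.
#' @export
compute_eh_ratio <- function(mask, hydrops_mi2_slice, organ_label = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    if (is.null(organ_label))
      abort_inearseg("organ_label needed with a segmentation_mask",
                     "inearseg_parameter_error")
    mask <- mask$labels == organ_label
  }
  mask <- mask != 0
  check_aligned(mask, hydrops_mi2_slice)
  p_seg <- sum(mask)
  p_neg <- sum(hydrops_mi2_slice[mask] < 0)
  structure(list(p_seg = as.integer(p_seg), p_neg = as.integer(p_neg),
                 ratio = if (p_seg > 0) p_neg / p_seg else NA_real_),
            class = "eh_result")
}

#' @export
print.eh_result <- function(x, ...) {
  cat(sprintf("<eh_result> p_seg %d, p_neg %d, EH ratio %s\n",
              x$p_seg, x$p_neg,
              if (is.na(x$ratio)) "NA (not detected)" else
                sprintf("%.4f", x$ratio)))
  invisible(x)
}

#' Ground-truth oracle segmenter
#'
#' A segmenter that answers [predict_patch()] queries from the stored
#' ground-truth masks of one or more studies instead of a network. Used to
#' test every pipeline stage downstream of segmentation in isolation and as
#' the upper-bound reference in evaluations.
#'
#' @param studies a [study_case()] with `gt_masks`, or a list of them.
#' @return An object of class `inear_gt_oracle` (also `inear_segmenter`).
#' @export
gt_oracle_segmenter <- function(studies) {
  if (inherits(studies, "study_case")) studies <- list(studies)
  env <- new.env(parent = emptyenv())
  for (st in studies) {
    if (is.null(st$gt_masks))
      abort_inearseg("oracle needs studies with gt_masks",
                     "inearseg_parameter_error")
    assign(st$subject_id, st$gt_masks, envir = env)
  }
  structure(list(masks = env),
            class = c("inear_gt_oracle", "inear_segmenter"))
}

#' @export
predict_patch.inear_gt_oracle <- function(model, triplet, ...) {
  if (!exists(triplet$subject_id, envir = model$masks))
    abort_inearseg(sprintf("no ground truth for subject '%s'",
                           triplet$subject_id),
                   "inearseg_parameter_error")
  gt <- get(triplet$subject_id, envir = model$masks)
  patch <- crop_patch(gt[, , triplet$main_slice_index + 1L],
                      triplet$ref["row"], triplet$ref["col"],
                      nrow(triplet$main))
  # per-side relabel: {1,2} are the left organs, {3,4} the right ones
  offs <- if (triplet$side == "left") c(1L, 2L) else c(3L, 4L)
  lab <- matrix(0L, nrow(patch), ncol(patch))
  lab[patch == offs[1]] <- 1L
  lab[patch == offs[2]] <- 2L
  segmentation_mask(lab, triplet$side, triplet$main_slice_index)
}

#' Run the full analysis on one study
#'
#' Composes HYDROPS and HYDROPS-Mi2, segments the full MRC stack with the
#' sliding three-slice window, selects the key slice per organ class, crops
#' the HYDROPS-Mi2 patch at each key slice with the same reference-point
#' convention as the MRC patches, and computes the four EH ratios.
#' Undetected organs appear in the report with `NA` ratio and a warning,
#' never an error, so batch runs always complete.
#'
#' @param study a [study_case()].
#' @param model a segmenter.
#' @return An object of class `inear_report`: per organ class a list with
#'   `detected`, `key_slice` (0-based), `p_seg`, `p_neg`, `eh_ratio`; plus
#'   `subject_id`, `n_slices` and the area `profiles`.
#' @export
run_pipeline <- function(study, model) {
  hyd <- compute_hydrops(study$ppi, study$pei)
  mi2 <- compute_hydrops_mi2(hyd, study$mrc)
  seg <- segment_stack(model, study$mrc, study$ref_points)
  organs <- list()
  for (org in ORGAN_CLASSES) {
    prof <- seg$profiles[[org]]
    side <- organ_side(org)
    if (!prof$detected) {
      warning(sprintf("%s: organ not detected (all areas zero)", org),
              call. = FALSE)
      organs[[org]] <- list(detected = FALSE, key_slice = NA_integer_,
                            p_seg = 0L, p_neg = 0L, eh_ratio = NA_real_)
      next
    }
    ki <- prof$key_index
    mask <- seg$masks[[side]][[ki]]        # masks[[k]] is main slice k
    rp <- study$ref_points[[side]]
    mi2_patch <- crop_patch(mi2$data[, , ki + 1L], rp$row, rp$col,
                            nrow(mask$labels))
    ehr <- compute_eh_ratio(mask, mi2_patch, organ_label = organ_label(org))
    organs[[org]] <- list(detected = TRUE, key_slice = ki,
                          p_seg = ehr$p_seg, p_neg = ehr$p_neg,
                          eh_ratio = ehr$ratio)
  }
  structure(list(subject_id = study$subject_id,
                 n_slices = n_slices(study$mrc),
                 organs = organs, profiles = seg$profiles),
            class = "inear_report")
}

#' @export
print.inear_report <- function(x, ...) {
  cat(sprintf("<inear_report> subject '%s' (%d slices)\n",
              x$subject_id, x$n_slices))
  for (org in names(x$organs)) {
    o <- x$organs[[org]]
    if (o$detected)
      cat(sprintf("  %-15s key slice %2d (1-based %2d)  p_seg %4d  p_neg %4d  EH ratio %.4f\n",
                  org, o$key_slice, o$key_slice + 1L, o$p_seg, o$p_neg,
                  o$eh_ratio))
    else
      cat(sprintf("  %-15s not detected\n", org))
  }
  invisible(x)
}

#' @export
plot.inear_report <- function(x, ...) {
  profs <- x$profiles
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (org in names(profs)) {
    p <- profs[[org]]
    idx <- seq_along(p$areas)          # main-slice indices, 0-based == value
    graphics::plot(idx, p$areas, type = "h", lwd = 3,
                   xlab = "main slice (0-based)", ylab = "segmented px",
                   main = org, ...)
    if (p$detected)
      graphics::points(p$key_index, p$key_area, pch = 19, col = 2)
  }
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Slice indices are written 1-based to match radiology viewers.
#'
#' @param report an `inear_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(subject_id = report$subject_id, n_slices = report$n_slices,
              organs = lapply(report$organs, function(o)
                list(detected = o$detected,
                     key_slice = if (o$detected) o$key_slice + 1L else NULL,
                     p_seg = o$p_seg, p_neg = o$p_neg,
                     eh_ratio = if (o$detected) o$eh_ratio else NULL)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
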