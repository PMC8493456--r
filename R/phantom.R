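#' Parameters of the synthetic inner-ear phantom
#'
#' The phantom emulates the geometry and signal relationships of an aligned
#' MRC/PPI/PEI inner-ear study: whole-brain-sized slices (default 384 x 324)
#' in which each ear's organs occupy well under 60 pixels across; a
#' cochlea-like annulus and a vestibule-like ellipse per side, drawn over
#' five consecutive slices with a unimodal area profile (unique maximum at
#' the designed key slice); and, inside each organ, a designated hydrops
#' subregion occupying fraction `rho` of the organ's pixels where PEI
#' exceeds PPI (so HYDROPS < 0 there) while the rest of the organ has
#' PPI > PEI. MRC is strictly positive everywhere, so HYDROPS-Mi2 preserves
#' the HYDROPS sign.
#'
#' Background noise is Gaussian truncated at +/- 3 SD; the signal levels are
#' validated to leave a margin larger than the worst-case truncated noise, so
#' the sign of HYDROPS is guaranteed by construction: negative exactly on the
#' designated hydrops pixels. That makes the designed EH ratios exact up to
#' pixel quantisation.
#'
#' @param n_slices,height,width stack geometry (defaults 24 x 384 x 324; use
#'   104 slices to exercise the full-length output-count law).
#' @param rho named per-organ designed EH fractions in `[0, 1]`.
#' @param mrc_fluid,mrc_background MRC signal inside organs / elsewhere.
#' @param ppi_perilymph,ppi_hydrops,ppi_background PPI signal levels.
#' @param pei_perilymph,pei_hydrops,pei_background PEI signal levels.
#' @param noise_sd SD of the truncated Gaussian noise.
#' @param profile_scales radius scale per organ slice (unimodal, unique max).
#' @param cochlea_outer,cochlea_inner annulus radii (px) at full scale.
#' @param vestibule_axes ellipse semi-axes (px) at full scale.
#' @param cochlea_offset,vestibule_offset organ centre offsets (row, col)
#'   from the side's reference point.
#' @param centre_jitter_px,ref_jitter_px per-subject jitter bounds.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(n_slices = 24L, height = 384L, width = 324L,
                           rho = c(left_cochlea = 0.35, left_vestibule = 0.20,
                                   right_cochlea = 0.25, right_vestibule = 0.10),
                           mrc_fluid = 100, mrc_background = 10,
                           ppi_perilymph = 80, ppi_hydrops = 20,
                           ppi_background = 20,
                           pei_perilymph = 20, pei_hydrops = 80,
                           pei_background = 5,
                           noise_sd = 2,
                           profile_scales = c(0.5, 0.72, 1, 0.72, 0.5),
                           cochlea_outer = 9, cochlea_inner = 4,
                           vestibule_axes = c(8, 6),
                           cochlea_offset = c(-12, -10),
                           vestibule_offset = c(10, 12),
                           centre_jitter_px = 3L, ref_jitter_px = 2L) {
  p <- structure(as.list(environment()), class = "phantom_params")
  p$n_slices <- as.integer(n_slices)
  p$height <- as.integer(height); p$width <- as.integer(width)
  if (p$n_slices < 7L)
    abort_inearseg("phantom needs at least 7 slices", "inearseg_parameter_error")
  if (p$height < PATCH_SIZE || p$width < PATCH_SIZE)
    abort_inearseg("phantom slices must be at least patch-sized",
                   "inearseg_parameter_error")
  if (!setequal(names(rho), ORGAN_CLASSES) || any(rho < 0) || any(rho > 1))
    abort_inearseg("rho must name the 4 organ classes with values in [0,1]",
                   "inearseg_parameter_error")
  m <- 6 * noise_sd                        # worst-case truncated-noise spread
  if (ppi_perilymph - pei_perilymph <= m ||
      pei_hydrops - ppi_hydrops <= m ||
      ppi_background - pei_background <= m ||
      mrc_background <= 3 * noise_sd || mrc_fluid <= 3 * noise_sd)
    abort_inearseg("signal levels leave no margin over the noise: the HYDROPS sign guarantee would break",
                   "inearseg_parameter_error")
  pk <- which.max(profile_scales)
  if (sum(profile_scales == max(profile_scales)) != 1L)
    abort_inearseg("profile_scales must have a unique maximum",
                   "inearseg_parameter_error")
  reach <- max(abs(cochlea_offset) + cochlea_outer,
               abs(vestibule_offset) + max(vestibule_axes)) +
    centre_jitter_px
  if (reach > 45)
    abort_inearseg("organs would overflow the patch window around the reference point",
                   "inearseg_parameter_error")
  p
}

# truncated gaussian noise, clipped at +/- 3 sd
trunc_noise <- function(n, sd) pmin(pmax(rnorm(n, 0, sd), -3 * sd), 3 * sd)

raster_annulus <- function(H, W, r0, c0, outer, inner) {
  rr <- pmax(1L, floor(r0 - outer)):pmin(H, ceiling(r0 + outer))
  cc <- pmax(1L, floor(c0 - outer)):pmin(W, ceiling(c0 + outer))
  d2 <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2)
  sel <- which(d2 <= outer^2 & d2 >= inner^2, arr.ind = TRUE)
  cbind(row = rr[sel[, 1]], col = cc[sel[, 2]])
}

raster_ellipse <- function(H, W, r0, c0, a, b) {
  rr <- pmax(1L, floor(r0 - a)):pmin(H, ceiling(r0 + a))
  cc <- pmax(1L, floor(c0 - b)):pmin(W, ceiling(c0 + b))
  v <- outer((rr - r0) / a, (cc - c0) / b, function(x, y) x^2 + y^2)
  sel <- which(v <= 1, arr.ind = TRUE)
  cbind(row = rr[sel[, 1]], col = cc[sel[, 2]])
}

#' Generate one synthetic phantom study
#'
#' Draws the four organs with per-subject jittered geometry, designates the
#' hydrops pixels so that the EH ratio measured on the ground-truth mask at
#' the key slice equals the designed `rho` up to pixel quantisation
#' (`|error| <= 1 / p_seg`), composes the three modality volumes with
#' truncated Gaussian noise, and returns the study with ground truth
#' attached. The realised design (key slices, exact per-organ ratios, areas)
#' is in `attr(study, "design")`.
#'
#' @param params a [phantom_params()].
#' @param subject_id subject identifier.
#' @param seed integer seed; fixed seed, identical study.
#' @param rho optional override of `params$rho`.
#' @param key_slices optional named 0-based key-slice overrides (must leave
#'   room for the five-slice organ profile).
#' @return A [study_case()] with `gt_masks`, `gt_key_slices`, reference
#'   points, and a `design` attribute.
#' @export
generate_study <- function(params = phantom_params(), subject_id = "phantom",
                           seed = 1L, rho = NULL, key_slices = NULL) {
  if (!inherits(params, "phantom_params"))
    abort_inearseg("params must be phantom_params", "inearseg_parameter_error")
  set.seed(seed)
  if (is.null(rho)) rho <- params$rho
  if (any(rho < 0) || any(rho > 1))
    abort_inearseg("rho must be in [0,1]", "inearseg_parameter_error")
  N <- params$n_slices; H <- params$height; W <- params$width
  half_span <- (length(params$profile_scales) - 1L) %/% 2L
  lo <- half_span; hi <- N - 1L - half_span          # leave room for profile
  lo <- max(lo, 1L); hi <- min(hi, N - 2L)           # key must be a main slice
  jit <- function(b) sample.int(2L * b + 1L, 1L) - b - 1L
  refs <- list(
    left = ref_point("left", 190L + jit(params$ref_jitter_px),
                     96L + jit(params$ref_jitter_px)),
    right = ref_point("right", 190L + jit(params$ref_jitter_px),
                      (params$width - 1L - 96L) + jit(params$ref_jitter_px)))
  if (is.null(key_slices)) {
    key_slices <- vapply(ORGAN_CLASSES, function(o)
      sample(seq.int(lo, hi), 1L), integer(1))
  } else {
    key_slices <- vapply(ORGAN_CLASSES, function(o)
      as.integer(key_slices[[o]]), integer(1))
    if (any(key_slices < lo) || any(key_slices > hi))
      abort_inearseg("key slices leave no room for the organ profile",
                     "inearseg_parameter_error")
  }
  gt <- array(0L, dim = c(H, W, N))
  hyd_mask <- array(FALSE, dim = c(H, W, N))
  design <- list()
  for (org in ORGAN_CLASSES) {
    side <- organ_side(org)
    rp <- refs[[side]]
    off <- if (organ_label(org) == 1L) params$cochlea_offset else params$vestibule_offset
    # inner-ear anatomy is mirror-symmetric: the right ear's layout is the
    # left ear's reflected in the column axis (this also makes horizontal
    # flip augmentation map one side onto the other consistently)
    if (side == "right") off <- c(off[1], -off[2])
    ctr <- c(rp$row + 1L + off[1] + jit(params$centre_jitter_px),
             rp$col + 1L + off[2] + jit(params$centre_jitter_px))  # 1-based
    ks <- key_slices[[org]]
    areas <- integer(N)
    label <- match(org, ORGAN_CLASSES)
    # hydrops blob grows from a fixed medial-superior anchor, mirrored with
    # the side
    anchor <- ctr + if (side == "right") c(-3, 3) else c(-3, -3)
    for (j in seq_along(params$profile_scales)) {
      sl <- ks + j - half_span - 1L   # 0-based slice
      if (sl < 0L || sl > N - 1L) next
      s <- params$profile_scales[j]
      px <- if (organ_label(org) == 1L)
        raster_annulus(H, W, ctr[1], ctr[2],
                       params$cochlea_outer * s, params$cochlea_inner * s)
      else
        raster_ellipse(H, W, ctr[1], ctr[2],
                       params$vestibule_axes[1] * s, params$vestibule_axes[2] * s)
      idx <- cbind(px, sl + 1L)
      if (any(gt[idx] != 0L))
        abort_inearseg("phantom organs overlap; reduce radii or offsets",
                       "inearseg_parameter_error")
      gt[idx] <- label
      areas[sl + 1L] <- nrow(px)
      k <- round(rho[[org]] * nrow(px))
      if (k > 0L) {
        d2 <- (px[, 1] - anchor[1])^2 + (px[, 2] - anchor[2])^2
        sel <- order(d2)[seq_len(k)]
        hyd_mask[cbind(px[sel, , drop = FALSE], sl + 1L)] <- TRUE
      }
    }
    main_areas <- areas[(1:(N - 2L)) + 1L]
    if (sum(main_areas == max(main_areas)) != 1L ||
        which.max(main_areas) != ks)
      abort_inearseg("phantom area profile lost its unique maximum",
                     "inearseg_parameter_error")
    S <- areas[ks + 1L]
    k_key <- round(rho[[org]] * S)
    design[[org]] <- list(key_slice = ks, rho_requested = unname(rho[[org]]),
                          rho_realized = k_key / S, p_seg = S,
                          areas = main_areas)
  }
  organ <- gt != 0L
  nvox <- H * W * N
  mrc <- array(params$mrc_background, dim = c(H, W, N))
  mrc[organ] <- params$mrc_fluid
  ppi <- array(params$ppi_background, dim = c(H, W, N))
  ppi[organ] <- params$ppi_perilymph
  ppi[hyd_mask] <- params$ppi_hydrops
  pei <- array(params$pei_background, dim = c(H, W, N))
  pei[organ] <- params$pei_perilymph
  pei[hyd_mask] <- params$pei_hydrops
  mrc <- mrc + trunc_noise(nvox, params$noise_sd)
  ppi <- ppi + trunc_noise(nvox, params$noise_sd)
  pei <- pei + trunc_noise(nvox, params$noise_sd)
  st <- study_case(subject_id,
                   volume_stack(mrc, "MRC", subject_id = subject_id),
                   volume_stack(ppi, "PPI", subject_id = subject_id),
                   volume_stack(pei, "PEI", subject_id = subject_id),
                   ref_points = refs, gt_masks = gt,
                   gt_key_slices = key_slices)
  attr(st, "design") <- design
  st
}

#' Generate a seeded phantom dataset
#'
#' Organ positions, key slices and designed EH fractions vary across
#' subjects; `rho` is drawn uniformly from `rho_range` per organ. The result
#' is deterministic for a fixed seed.
#'
#' @param n_subjects number of phantom subjects (>= 1).
#' @param params template [phantom_params()].
#' @param seed master seed; subject `i` uses `seed + 7919 * i`.
#' @param rho_range length-2 bounds of the designed EH fraction.
#' @return list of [study_case()]s (each with its `design` attribute).
#' @export
generate_dataset <- function(n_subjects, params = phantom_params(),
                             seed = 1L, rho_range = c(0.05, 0.6)) {
  if (n_subjects < 1L)
    abort_inearseg("n_subjects must be >= 1", "inearseg_parameter_error")
  lapply(seq_len(n_subjects), function(i) {
    set.seed(seed + 7919L * i)
    rho <- stats::setNames(runif(4, rho_range[1], rho_range[2]),
                           ORGAN_CLASSES)
    generate_study(params, subject_id = sprintf("phantom%03d", i),
                   seed = seed + 7919L * i + 1L, rho = rho)
  })
}

#' Build annotated training samples from a phantom study
#'
#' `selective` samples are the triplets at each side's ground-truth key
#' slices (one per unique key slice and side), labelled with the full
#' per-side mask of that slice -- the analogue of physician key-slice
#' annotation. `full` samples cover every main slice whose patch intersects
#' an organ.
#'
#' @param study a [study_case()] with ground truth.
#' @return list of [annotated_sample()]s.
#' @export
make_training_samples <- function(study) {
  oracle <- gt_oracle_segmenter(study)
  N <- n_slices(study$mrc)
  out <- list()
  for (side in c("left", "right")) {
    orgs <- ORGAN_CLASSES[organ_side(ORGAN_CLASSES) == side]
    keys <- unique(unlist(study$gt_key_slices[orgs]))
    organ_slices <- sort(unique(unlist(lapply(orgs, function(org) {
      which(apply(study$gt_masks == match(org, ORGAN_CLASSES), 3, any)) - 1L
    }))))
    organ_slices <- organ_slices[organ_slices >= 1L & organ_slices <= N - 2L]
    for (i in organ_slices) {
      tr <- extract_patch_triplet(study$mrc, study$ref_points[[side]], i)
      lab <- predict_patch(oracle, tr)
      mode <- if (i %in% keys) "selective" else "full"
      out[[length(out) + 1L]] <- annotated_sample(tr, lab, mode)
    }
  }
  out
}
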