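#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|` over pixels. Two empty masks score 1.0
#' (perfect vacuous agreement) with a message, so degenerate phantom cases do
#' not produce NaN.
#'
#' @param gt,pred logical/0-1 matrices of identical shape, or
#'   [segmentation_mask()]s (compared at `organ_label`).
#' @param organ_label when masks are [segmentation_mask()]s: 1 = cochlea,
#'   2 = vestibule.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(gt, pred, organ_label = NULL) {
  if (inherits(gt, "segmentation_mask")) gt <- gt$labels == organ_label
  if (inherits(pred, "segmentation_mask")) pred <- pred$labels == organ_label
  gt <- gt != 0; pred <- pred != 0
  check_aligned(gt, pred)
  uni <- sum(gt | pred)
  if (uni == 0) {
    message("both masks empty: IoU defined as 1")
    return(1)
  }
  sum(gt & pred) / uni
}

#' Single-score two-way intraclass correlation coefficient
#'
#' Agreement between two raters scoring the same subjects, computed from the
#' two-way ANOVA mean squares. The default is the two-way random-effects,
#' absolute-agreement, single-measurement form ICC(2,1):
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)}
#' with `n` subjects, `k = 2` raters, `MS_R` the between-subject, `MS_C` the
#' between-rater and `MS_E` the residual mean square. `type = "consistency"`
#' gives ICC(3,1), which ignores systematic rater offsets.
#'
#' @param rater_a,rater_b numeric vectors of paired scores, length >= 2.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return The ICC (a scalar, at most 1; can be negative).
#' @export
icc_single_two_way <- function(rater_a, rater_b,
                               type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(rater_a) != length(rater_b))
    abort_inearseg("rater series differ in length", "inearseg_pairing_error")
  n <- length(rater_a)
  if (n < 2L)
    abort_inearseg("need at least 2 paired scores", "inearseg_undefined_error")
  if (!all(is.finite(rater_a)) || !all(is.finite(rater_b)))
    abort_inearseg("scores must be finite", "inearseg_undefined_error")
  x <- cbind(rater_a, rater_b)
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot  <- sum((x - grand)^2)
  ss_err  <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- switch(type,
    agreement   = msr + (k - 1) * mse + k * (msc - mse) / n,
    consistency = msr + (k - 1) * mse)
  if (abs(denom) < .Machine$double.eps * max(1, abs(msr)))
    abort_inearseg("zero total variance: ICC undefined",
                   "inearseg_undefined_error")
  (msr - mse) / denom
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over the textbook formula with the degenerate cases turned
#' into classed errors.
#'
#' @param x,y numeric vectors of equal length >= 2, non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    abort_inearseg("series differ in length", "inearseg_pairing_error")
  if (length(x) < 2L)
    abort_inearseg("need at least 2 observations", "inearseg_undefined_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_inearseg("constant series: correlation undefined",
                   "inearseg_undefined_error")
  stats::cor(x, y, method = "pearson")
}

#' Slice-distance histogram between system and reference key slices
#'
#' For each organ, the absolute difference between the system-selected and
#' the reference key-slice index; counts are reported per distance with
#' cumulative percentages rounded to one decimal.
#'
#' @param pred,gt named integer vectors (organ identifier -> slice index);
#'   names must match.
#' @return A `distance_histogram` object, see [distance_histogram()].
#' @export
slice_distance_histogram <- function(pred, gt) {
  if (is.null(names(pred)) || is.null(names(gt)) ||
      !setequal(names(pred), names(gt)) ||
      anyDuplicated(names(pred)) || anyDuplicated(names(gt)))
    abort_inearseg("pred and gt must be named by the same organ keys",
                   "inearseg_pairing_error")
  d <- abs(pred - gt[names(pred)])
  tab <- table(factor(d, levels = 0:max(d)))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  distance_histogram(counts)
}

#' Build a distance-histogram report from per-distance counts
#'
#' @param counts integer vector of organ counts; element `i` is distance
#'   `i - 1` (or use names `"0"`, `"1"`, ...).
#' @return An object of class `distance_histogram` with a `table`
#'   (data.frame: distance, count, cumulative, cumulative_pct) and `total`.
#' @export
distance_histogram <- function(counts) {
  counts <- as.integer(counts)
  total <- sum(counts)
  if (total == 0L)
    abort_inearseg("no organs counted", "inearseg_pairing_error")
  cum <- cumsum(counts)
  tab <- data.frame(distance = seq_along(counts) - 1L,
                    count = counts, cumulative = cum,
                    cumulative_pct = round(100 * cum / total, 1))
  structure(list(table = tab, total = total), class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("<distance_histogram> %d organs\n", x$total))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Agreement report between expert and system EH ratios
#'
#' Bundles the agreement statistics the protocol reports: the single-score
#' two-way ICC over all organ ratios, the same ICC restricted to cochleae
#' and to vestibules (when an organ labelling is supplied), and the Pearson
#' correlation.
#'
#' @param expert,system paired numeric ratio series.
#' @param organ optional character vector naming each pair's organ class
#'   (matched on `"cochlea"` / `"vestibule"`).
#' @param type ICC form, see [icc_single_two_way()].
#' @return An object of class `agreement_report` with fields `icc_all`,
#'   `icc_cochlea`, `icc_vestibule` (NA without organ labels), `pearson_r`,
#'   `n_pairs`.
#' @export
agreement_report <- function(expert, system, organ = NULL,
                             type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(expert) != length(system))
    abort_inearseg("series differ in length", "inearseg_pairing_error")
  out <- list(icc_all = icc_single_two_way(expert, system, type),
              icc_cochlea = NA_real_, icc_vestibule = NA_real_,
              pearson_r = pearson(expert, system),
              n_pairs = length(expert))
  if (!is.null(organ)) {
    if (length(organ) != length(expert))
      abort_inearseg("organ labels differ in length",
                     "inearseg_pairing_error")
    for (part in c("cochlea", "vestibule")) {
      sel <- grepl(part, organ)
      if (sum(sel) >= 2L)
        out[[paste0("icc_", part)]] <-
          icc_single_two_way(expert[sel], system[sel], type)
    }
  }
  structure(out, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d pairs\n", x$n_pairs))
  cat(sprintf("  ICC all %.3f  cochlea %s  vestibule %s  Pearson r %.3f\n",
              x$icc_all,
              ifelse(is.na(x$icc_cochlea), "NA", sprintf("%.3f", x$icc_cochlea)),
              ifelse(is.na(x$icc_vestibule), "NA", sprintf("%.3f", x$icc_vestibule)),
              x$pearson_r))
  invisible(x)
}

#' Per-organ IoU of a segmenter at the ground-truth key slices
#'
#' For every organ of every study, predicts the mask at the ground-truth key
#' slice and scores it against the ground-truth patch crop.
#'
#' @param model a segmenter.
#' @param studies list of [study_case()]s with `gt_masks` and
#'   `gt_key_slices`.
#' @return data.frame with columns `subject_id`, `organ`, `key_slice`,
#'   `iou`.
#' @export
evaluate_segmentation <- function(model, studies) {
  if (inherits(studies, "study_case")) studies <- list(studies)
  rows <- list()
  for (st in studies) {
    if (is.null(st$gt_masks) || is.null(st$gt_key_slices))
      abort_inearseg("evaluation needs gt_masks and gt_key_slices",
                     "inearseg_parameter_error")
    oracle <- gt_oracle_segmenter(st)
    for (org in ORGAN_CLASSES) {
      ks <- st$gt_key_slices[[org]]
      side <- organ_side(org)
      tr <- extract_patch_triplet(st$mrc, st$ref_points[[side]], ks)
      pred <- predict_patch(model, tr)
      gtm <- predict_patch(oracle, tr)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = st$subject_id, organ = org, key_slice = ks,
                   iou = iou(gtm, pred, organ_label = organ_label(org)))
    }
  }
  do.call(rbind, rows)
}

#' Subject-level k-fold cross-validation of a segmenter
#'
#' Subjects (never slices) are partitioned into `k` folds so no subject's
#' slices leak between training and validation. For each fold, `trainer` is
#' called on the training studies and the returned segmenter is scored with
#' [evaluate_segmentation()] on the held-out studies.
#'
#' @param studies list of [study_case()]s with ground truth.
#' @param trainer `function(train_studies) -> segmenter`; when omitted, a
#'   network of architecture `spec` is trained per fold with
#'   [train_curriculum()] under `config`.
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param spec,config [network_spec()] and [training_config()] for the
#'   default trainer; ignored when `trainer` is given.
#' @return An `iou_report`: per-fold mean IoU, overall `mean` and `sd`, and
#'   the per-organ results table.
#' @export
crossvalidate <- function(studies, trainer = NULL, k = 5L, seed = 1L,
                          spec = NULL, config = training_config()) {
  if (is.null(trainer)) {
    if (is.null(spec))
      abort_inearseg("supply either a trainer or a network spec",
                     "inearseg_config_error")
    trainer <- function(trn) {
      samps <- unlist(lapply(trn, make_training_samples), recursive = FALSE)
      train_curriculum(samps, spec, config)
    }
  }
  n <- length(studies)
  if (n < k)
    abort_inearseg(sprintf("%d subjects cannot fill %d folds", n, k),
                   "inearseg_split_error")
  folds <- make_folds(vapply(studies, function(s) s$subject_id, character(1)),
                      k, seed)
  res <- list(); fold_mean <- numeric(k)
  for (f in seq_len(k)) {
    val <- studies[folds == f]
    trn <- studies[folds != f]
    model <- trainer(trn)
    ev <- evaluate_segmentation(model, val)
    ev$fold <- f
    res[[f]] <- ev
    fold_mean[f] <- mean(ev$iou)
  }
  tab <- do.call(rbind, res)
  structure(list(fold_mean = fold_mean, mean = mean(fold_mean),
                 sd = stats::sd(fold_mean), results = tab, k = k,
                 folds = folds),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> %d-fold cross-validation: mean IoU %.3f (SD %.3f)\n",
              x$k, x$mean, x$sd))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_mean), collapse = ", "),
      "\n")
  invisible(x)
}

#' Seeded subject-level fold assignment
#'
#' @param ids subject identifiers.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold label per subject (1..k); folds are disjoint, cover
#'   all subjects and differ in size by at most one.
#' @export
make_folds <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (n < k)
    abort_inearseg(sprintf("%d subjects cannot fill %d folds", n, k),
                   "inearseg_split_error")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
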