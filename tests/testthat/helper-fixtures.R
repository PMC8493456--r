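# Shared fixtures, built once per test run. Phantom stacks use fewer slices
# than the 24-slice default purely to keep the suite fast; in-plane geometry
# and signal levels are the generator defaults.

fix_params <- function(n_slices = 12L) phantom_params(n_slices = n_slices)

.fix_cache <- new.env(parent = emptyenv())

fix_study <- function() {
  if (is.null(.fix_cache$study))
    .fix_cache$study <- generate_study(fix_params(), "fix01", seed = 101L)
  .fix_cache$study
}

fix_dataset <- function(n = 5L) {
  key <- paste0("ds", n)
  if (is.null(.fix_cache[[key]]))
    .fix_cache[[key]] <- generate_dataset(n, fix_params(), seed = 202L)
  .fix_cache[[key]]
}

tiny_spec <- function(depth = 2L, base = 4L)
  network_spec("three_into_unet", depth = depth, base_channels = base,
               dropout_rate = 0)

# brute-force EH counting oracle: explicit pixel loop, independent of the
# vectorised implementation
eh_ratio_bruteforce <- function(mask, img) {
  p_seg <- 0L; p_neg <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) {
      p_seg <- p_seg + 1L
      if (img[i, j] < 0) p_neg <- p_neg + 1L
    }
  }
  list(p_seg = p_seg, p_neg = p_neg,
       ratio = if (p_seg > 0) p_neg / p_seg else NA_real_)
}

# ICC(2,1)/ICC(3,1) oracle from stats::aov mean squares
icc_aov_oracle <- function(a, b, type = "agreement") {
  n <- length(a); k <- 2
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  den <- if (type == "agreement")
    msr + (k - 1) * mse + k * (msc - mse) / n
  else msr + (k - 1) * mse
  (msr - mse) / den
}

# mirror a study left-right (images, reference points and ground truth)
mirror_study <- function(st) {
  W <- dim(st$mrc$data)[2]
  flip <- function(a) a[, rev(seq_len(W)), , drop = FALSE]
  gt <- flip(st$gt_masks)
  gtm <- gt
  gtm[gt == 1L] <- 3L; gtm[gt == 2L] <- 4L
  gtm[gt == 3L] <- 1L; gtm[gt == 4L] <- 2L
  mir_col <- function(c) W - 1L - c
  refs <- list(
    left = ref_point("left", st$ref_points$right$row,
                     mir_col(st$ref_points$right$col)),
    right = ref_point("right", st$ref_points$left$row,
                      mir_col(st$ref_points$left$col)))
  ks <- st$gt_key_slices
  ksm <- ks[c("right_cochlea", "right_vestibule",
              "left_cochlea", "left_vestibule")]
  names(ksm) <- c("left_cochlea", "left_vestibule",
                  "right_cochlea", "right_vestibule")
  study_case(paste0(st$subject_id, "_mir"),
             volume_stack(flip(st$mrc$data), "MRC",
                          subject_id = paste0(st$subject_id, "_mir")),
             volume_stack(flip(st$ppi$data), "PPI",
                          subject_id = paste0(st$subject_id, "_mir")),
             volume_stack(flip(st$pei$data), "PEI",
                          subject_id = paste0(st$subject_id, "_mir")),
             ref_points = refs, gt_masks = gtm, gt_key_slices = ksm)
}
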