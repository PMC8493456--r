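test_that("IoU matches the pixel-set definition", {
  a <- matrix(FALSE, 8, 8); a[1:2, 1:5] <- TRUE       # 10 px
  b <- matrix(FALSE, 8, 8); b[2:3, 1:5] <- TRUE       # 10 px, overlap 5
  expect_equal(iou(a, b), 5 / 15)
  expect_equal(iou(a, a), 1)
  d <- matrix(FALSE, 8, 8); d[6:7, 6:8] <- TRUE
  expect_equal(iou(a, d), 0)
  # symmetry and range on random masks
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(runif(64) < 0.4, 8, 8)
    y <- matrix(runif(64) < 0.4, 8, 8)
    v <- iou(x, y)
    expect_equal(v, iou(y, x))
    expect_true(v >= 0 && v <= 1)
  }
  expect_message(v0 <- iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
                 "both masks empty")
  expect_equal(v0, 1)
  expect_error(iou(a, matrix(FALSE, 7, 8)),
               class = "inearseg_alignment_error")
})

test_that("ICC(2,1) follows the two-way mean-squares definition", {
  expect_equal(icc_single_two_way(c(1, 2, 3), c(1, 2, 3)), 1)
  # constant offset: absolute agreement penalises, consistency does not
  a <- c(1, 2, 3, 4); b <- a + 1
  expect_lt(icc_single_two_way(a, b), 1)
  expect_equal(icc_single_two_way(a, b, type = "consistency"), 1)
  # reversed ranking gives a negative ICC
  expect_lt(icc_single_two_way(c(1, 2, 3), c(3, 2, 1)), 0)
  # agreement with an independent aov-based oracle
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(4:20, 1))
    y <- 0.8 * x + rnorm(length(x), sd = 0.5)
    expect_equal(icc_single_two_way(x, y), icc_aov_oracle(x, y),
                 tolerance = 1e-10)
    expect_equal(icc_single_two_way(x, y, "consistency"),
                 icc_aov_oracle(x, y, "consistency"), tolerance = 1e-10)
    expect_lte(icc_single_two_way(x, y), 1)
  }
  expect_error(icc_single_two_way(1, 2), class = "inearseg_undefined_error")
  expect_error(icc_single_two_way(c(1, 1), c(1, 1)),
               class = "inearseg_undefined_error")
  expect_error(icc_single_two_way(1:3, 1:4), class = "inearseg_pairing_error")
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(2, 1, 5, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), hand)
  expect_error(pearson(x, rep(1, 4)), class = "inearseg_undefined_error")
})

test_that("slice-distance histograms count and accumulate correctly", {
  # perfect selection: everything at distance 0
  p <- c(a = 3L, b = 7L); g <- c(a = 3L, b = 7L)
  h <- slice_distance_histogram(p, g)
  expect_equal(h$table$cumulative_pct[1], 100)
  expect_equal(h$total, 2L)
  # randomised maps against a per-organ loop oracle
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    keys <- paste0("o", seq_len(n))
    pred <- stats::setNames(sample(0:12, n, TRUE), keys)
    gt <- stats::setNames(sample(0:12, n, TRUE), keys)
    h <- slice_distance_histogram(pred, gt)
    dd <- integer(n)
    for (k in seq_len(n)) dd[k] <- abs(pred[[keys[k]]] - gt[[keys[k]]])
    for (r in seq_len(nrow(h$table)))
      expect_equal(h$table$count[r], sum(dd == h$table$distance[r]))
    expect_equal(sum(h$table$count), n)                 # conservation
    expect_true(all(diff(h$table$cumulative_pct) >= 0)) # non-decreasing
    expect_equal(tail(h$table$cumulative_pct, 1), 100)
  }
  expect_error(slice_distance_histogram(c(a = 1L), c(b = 1L)),
               class = "inearseg_pairing_error")
})

test_that("agreement reports split the ICC by organ type", {
  set.seed(51)
  organ <- rep(c("left_cochlea", "left_vestibule",
                 "right_cochlea", "right_vestibule"), 6)
  expert <- runif(24, 0, 0.6)
  system <- expert + rnorm(24, sd = 0.02)
  ar <- agreement_report(expert, system, organ)
  expect_equal(ar$n_pairs, 24L)
  is_c <- grepl("cochlea", organ)
  expect_equal(ar$icc_all, icc_single_two_way(expert, system))
  expect_equal(ar$icc_cochlea,
               icc_single_two_way(expert[is_c], system[is_c]))
  expect_equal(ar$icc_vestibule,
               icc_single_two_way(expert[!is_c], system[!is_c]))
  expect_equal(ar$pearson_r, pearson(expert, system))
  expect_gt(ar$icc_all, 0.9)
  # without organ labels the per-organ entries stay NA
  ar2 <- agreement_report(expert, system)
  expect_true(is.na(ar2$icc_cochlea) && is.na(ar2$icc_vestibule))
  expect_error(agreement_report(expert, system[-1]),
               class = "inearseg_pairing_error")
})

test_that("cross-validation folds partition subjects and the oracle is perfect", {
  ids <- paste0("s", 1:10)
  f <- make_folds(ids, 5L, seed = 3L)
  expect_length(f, 10L)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))                       # disjoint cover
  expect_identical(f, make_folds(ids, 5L, seed = 3L))   # reproducible
  expect_false(identical(f, make_folds(ids, 5L, seed = 4L)))
  expect_error(make_folds(ids[1:3], 5L), class = "inearseg_split_error")

  studies <- fix_dataset(5L)
  cv <- crossvalidate(studies, trainer = function(trn)
    gt_oracle_segmenter(studies), k = 5L, seed = 2L)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  expect_equal(sort(unique(cv$folds)), 1:5)
  # every subject appears in exactly one validation fold
  expect_equal(sort(unique(cv$results$subject_id)),
               sort(vapply(studies, function(s) s$subject_id, character(1))))
  # without a trainer a network spec is required
  expect_error(crossvalidate(studies, k = 5L),
               class = "inearseg_config_error")
})
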