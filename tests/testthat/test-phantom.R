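test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_study(fix_params(8L), "d", seed = 55L)
  b <- generate_study(fix_params(8L), "d", seed = 55L)
  expect_identical(a$mrc$data, b$mrc$data)
  expect_identical(a$pei$data, b$pei$data)
  expect_identical(a$gt_masks, b$gt_masks)
  expect_identical(attr(a, "design"), attr(b, "design"))
  c2 <- generate_study(fix_params(8L), "d", seed = 56L)
  expect_false(identical(a$mrc$data, c2$mrc$data))
})

test_that("phantom studies satisfy the geometric and signal invariants", {
  st <- fix_study()
  gt <- st$gt_masks
  # organs are small: every organ's in-plane extent stays under 60 px
  for (lab in 1:4) {
    idx <- which(apply(gt == lab, c(1, 2), any), arr.ind = TRUE)
    expect_lt(max(apply(idx, 2, function(v) diff(range(v)))), 60)
  }
  # MRC strictly positive everywhere (so Mi2 preserves the HYDROPS sign)
  expect_true(all(st$mrc$data > 0))
  # unimodal area profile with the designed unique maximum, per organ
  d <- attr(st, "design")
  for (org in names(d)) {
    areas <- d[[org]]$areas
    expect_equal(sum(areas == max(areas)), 1L)
    sel <- select_key_slice(areas)
    expect_equal(sel$position, d[[org]]$key_slice)
  }
})

test_that("HYDROPS is negative exactly on the designated hydrops pixels", {
  st <- fix_study()
  hyd <- compute_hydrops(st$ppi, st$pei)$data
  gt <- st$gt_masks
  # nowhere negative outside organs
  expect_true(all(hyd[gt == 0L] > 0))
  # inside each organ, the per-slice negative count equals round(rho * area)
  d <- attr(st, "design")
  for (lab in 1:4) {
    org <- c("left_cochlea", "left_vestibule",
             "right_cochlea", "right_vestibule")[lab]
    rho <- d[[org]]$rho_requested
    for (sl in seq_len(dim(gt)[3])) {
      m <- gt[, , sl] == lab
      if (!any(m)) next
      expect_equal(sum(hyd[, , sl][m] < 0), round(rho * sum(m)))
    }
  }
  # Mi2 sign matches HYDROPS sign on organ pixels
  mi2 <- compute_hydrops_mi2(hyd, st$mrc$data)
  expect_true(all(sign(mi2[gt > 0L]) == sign(hyd[gt > 0L])))
})

test_that("rho = 0 phantoms have identically zero EH ratios", {
  p <- fix_params(8L)
  st <- generate_study(p, "z", seed = 5L,
                       rho = stats::setNames(rep(0, 4),
                                             names(p$rho)))
  rep <- run_pipeline(st, gt_oracle_segmenter(st))
  for (o in rep$organs) expect_equal(o$eh_ratio, 0)
})

test_that("generated datasets vary and respect the requested rho range", {
  ds <- generate_dataset(12L, fix_params(7L), seed = 77L,
                         rho_range = c(0.1, 0.5))
  expect_length(ds, 12L)
  rho <- unlist(lapply(ds, function(s)
    vapply(attr(s, "design"), `[[`, numeric(1), "rho_requested")))
  expect_gte(min(rho), 0.1)
  expect_lte(max(rho), 0.5)
  expect_gt(diff(range(rho)), 0.2)      # actually spread over the range
  ids <- vapply(ds, function(s) s$subject_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  # determinism of the whole dataset
  ds2 <- generate_dataset(12L, fix_params(7L), seed = 77L,
                          rho_range = c(0.1, 0.5))
  expect_identical(ds[[7]]$mrc$data, ds2[[7]]$mrc$data)
})

test_that("training-sample extraction separates selective and full annotation", {
  st <- fix_study()
  samps <- make_training_samples(st)
  modes <- vapply(samps, function(s) s$annotation_mode, character(1))
  expect_true(all(c("selective", "full") %in% modes))
  keys <- st$gt_key_slices
  for (s in samps) {
    side <- s$triplet$side
    orgs <- paste0(side, c("_cochlea", "_vestibule"))
    if (s$annotation_mode == "selective")
      expect_true(s$triplet$main_slice_index %in% keys[orgs])
    # labels match the oracle crop at that slice
    expect_true(all(s$label$labels %in% 0:2))
    expect_gt(sum(s$label$labels > 0), 0)
  }
})
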