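test_that("HYDROPS subtraction matches an element-wise loop oracle", {
  set.seed(4)
  ppi <- array(rnorm(4 * 8 * 8, 50, 10), c(4, 8, 8))
  pei <- array(rnorm(4 * 8 * 8, 50, 10), c(4, 8, 8))
  h <- compute_hydrops(ppi, pei)
  oracle <- array(0, dim(ppi))
  for (i in 1:4) for (j in 1:8) for (k in 1:8)
    oracle[i, j, k] <- ppi[i, j, k] - pei[i, j, k]
  expect_equal(h, oracle)
  expect_equal(compute_hydrops(ppi, ppi), array(0, dim(ppi)))
  expect_equal(compute_hydrops(array(3, c(2, 2, 2)), array(5, c(2, 2, 2))),
               array(-2, c(2, 2, 2)))
  # anti-symmetry
  expect_equal(compute_hydrops(pei, ppi), -h)
  expect_error(compute_hydrops(ppi, array(0, c(4, 8, 7))),
               class = "inearseg_alignment_error")
})

test_that("HYDROPS-Mi2 multiplies voxel-wise and preserves sign under positive MRC", {
  set.seed(5)
  hyd <- array(rnorm(3 * 6 * 6), c(3, 6, 6))
  mrc <- array(runif(3 * 6 * 6, 0.5, 2), c(3, 6, 6))
  mi2 <- compute_hydrops_mi2(hyd, mrc)
  expect_equal(mi2, hyd * mrc)
  expect_true(all(sign(mi2) == sign(hyd)))
  expect_equal(compute_hydrops_mi2(hyd, array(1, dim(hyd))), hyd)
  expect_equal(compute_hydrops_mi2(array(-2, c(2, 2, 3)),
                                   array(3, c(2, 2, 3))),
               array(-6, c(2, 2, 3)))
})

test_that("volume_stack inputs yield tagged composed stacks", {
  st <- fix_study()
  h <- compute_hydrops(st$ppi, st$pei)
  expect_s3_class(h, "volume_stack")
  expect_identical(h$modality, "HYDROPS")
  m <- compute_hydrops_mi2(h, st$mrc)
  expect_identical(m$modality, "HYDROPS_MI2")
  expect_equal(m$data, (st$ppi$data - st$pei$data) * st$mrc$data)
})

test_that("patch triplets crop at the documented reference convention", {
  st <- fix_study()
  rp <- st$ref_points$left
  tr <- extract_patch_triplet(st$mrc, rp, 5L)
  # reference pixel sits at patch index (49,49) 0-based
  expect_equal(tr$main[50, 50], st$mrc$data[rp$row + 1L, rp$col + 1L, 6L])
  # interior crop equals manual slicing of all three slices
  rows <- (rp$row - 49L):(rp$row + 50L) + 1L
  cols <- (rp$col - 49L):(rp$col + 50L) + 1L
  expect_equal(tr$prev, st$mrc$data[rows, cols, 5L])
  expect_equal(tr$main, st$mrc$data[rows, cols, 6L])
  expect_equal(tr$nxt,  st$mrc$data[rows, cols, 7L])
  # determinism / idempotence
  tr2 <- extract_patch_triplet(st$mrc, rp, 5L)
  expect_identical(tr, tr2)
})

test_that("out-of-bounds crops are zero-padded with a warning", {
  st <- fix_study()
  edge <- ref_point("left", 10, 10)
  expect_warning(crop_patch(st$mrc$data[, , 5L], 10, 10), "zero-filled")
  tr <- suppressWarnings(extract_patch_triplet(st$mrc, edge, 4L))
  # rows/cols before the image start are zero
  expect_true(all(tr$main[1:39, ] == 0))
  expect_true(all(tr$main[, 1:39] == 0))
  # the in-image part matches the source: patch (40,40).. maps to pixel (0,0)..
  expect_equal(tr$main[40:100, 40:100],
               st$mrc$data[1:61, 1:61, 5L])
})

test_that("stack-boundary main slices are rejected", {
  st <- fix_study()
  N <- n_slices(st$mrc)
  expect_error(extract_patch_triplet(st$mrc, st$ref_points$left, 0L),
               class = "inearseg_boundary_error")
  expect_error(extract_patch_triplet(st$mrc, st$ref_points$left, N - 1L),
               class = "inearseg_boundary_error")
  expect_s3_class(extract_patch_triplet(st$mrc, st$ref_points$left, N - 2L),
                  "patch_triplet")
})
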