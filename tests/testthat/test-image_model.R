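test_that("volume_stack enforces its invariants", {
  ok <- array(1, c(120, 120, 3))
  expect_s3_class(volume_stack(ok, "MRC"), "volume_stack")
  bad <- ok; bad[1] <- NA
  expect_error(volume_stack(bad, "MRC"), class = "inearseg_shape_error")
  expect_error(volume_stack(array(1, c(120, 120, 2)), "MRC"),
               class = "inearseg_stack_error")
  expect_error(volume_stack(array(1, c(50, 120, 3)), "MRC"),
               class = "inearseg_shape_error")
  expect_error(volume_stack(ok, "T1"))
})

test_that("misaligned modality stacks are rejected at study construction", {
  a <- volume_stack(array(1, c(120, 120, 4)), "PPI")
  b <- volume_stack(array(1, c(120, 120, 3)), "PEI")
  m <- volume_stack(array(1, c(120, 120, 4)), "MRC")
  refs <- list(left = ref_point("left", 60, 30),
               right = ref_point("right", 60, 90))
  expect_error(study_case("s", m, a, b, refs),
               class = "inearseg_alignment_error")
})

test_that("a phantom study written to NIfTI reloads with identical voxels", {
  st <- fix_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  st2 <- read_study(dir)
  expect_equal(dim(st2$mrc$data), dim(st$mrc$data))
  for (m in c("mrc", "ppi", "pei"))
    expect_lt(max(abs(st2[[m]]$data - st[[m]]$data)),
              1e-6 * max(1, max(abs(st[[m]]$data))))
  expect_identical(st2$ref_points$left$row, st$ref_points$left$row)
  expect_identical(st2$ref_points$right$col, st$ref_points$right$col)
})

test_that("mean subtraction removes the mean, by hand and in general", {
  expect_equal(mean_subtract(matrix(7, 5, 5)), matrix(0, 5, 5))
  expect_equal(mean_subtract(matrix(c(1, 5, 3, 7), 2)),
               matrix(c(-3, 1, -1, 3), 2))           # mean = 4
  set.seed(9)
  for (i in 1:10) {
    p <- matrix(rnorm(64, mean = runif(1, -5, 5)), 8)
    q <- mean_subtract(p)
    expect_lt(abs(mean(q)), 1e-6)
    expect_equal(mean_subtract(q), q)                # idempotent
    expect_equal(dim(q), dim(p))
  }
  expect_error(mean_subtract(matrix(c(1, Inf), 1)),
               class = "inearseg_shape_error")
})
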