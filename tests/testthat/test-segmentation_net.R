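make_triplet <- function(fill = 0, size = 100L) {
  structure(list(prev = matrix(fill, size, size),
                 main = matrix(fill, size, size),
                 nxt = matrix(fill, size, size),
                 side = "left", main_slice_index = 1L,
                 subject_id = "t", ref = c(row = 50L, col = 50L)),
            class = "patch_triplet")
}

test_that("the forward pass yields a normalised 3-class probability map", {
  net <- build_network(tiny_spec(), seed = 3L)
  p <- patch_probabilities(net, make_triplet(0))
  expect_equal(dim(p), c(100L, 100L, 3L))
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
  expect_true(all(p >= 0 & p <= 1))
  # degenerate input: main patch duplicated into all three slots is still valid
  tr <- make_triplet(0)
  set.seed(1); tr$main <- matrix(rnorm(1e4), 100)
  tr$prev <- tr$main; tr$nxt <- tr$main
  p2 <- patch_probabilities(net, tr)
  expect_true(all(abs(apply(p2, c(1, 2), sum) - 1) < 1e-5))
  m <- predict_patch(net, tr)
  expect_true(all(m$labels %in% 0:2))
  expect_identical(predict_patch(net, tr)$labels, m$labels)  # deterministic
})

# analytic layer-by-layer parameter count, written independently of the
# engine's internal bookkeeping
analytic_param_count <- function(variant, depth, base, K = 3) {
  ch <- base * 2^(0:depth)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  total <- 0
  for (b in 1:3) {
    cin <- 1
    for (l in 1:depth) {
      c <- ch[l]
      total <- total + if (variant == "unet")
        conv(3, cin, c) + conv(3, c, c)
      else
        conv(1, cin, c / 2) + conv(3, cin, c / 4) +
          conv(3, cin, c / 4) + conv(3, c / 4, c / 4)
      cin <- c
    }
  }
  total <- total + conv(3, ch[depth], ch[depth + 1]) +
    conv(3, ch[depth + 1], ch[depth + 1])
  for (l in depth:1)
    total <- total + (4 * ch[l + 1] * ch[l] + ch[l]) +
      conv(3, 2 * ch[l], ch[l]) + conv(3, ch[l], ch[l])
  total + conv(1, ch[1], K)
}

test_that("parameter counts match a hand-computed layer-by-layer total", {
  s <- network_spec("three_into_unet", depth = 4L, base_channels = 16L)
  expect_equal(n_parameters(s), analytic_param_count("unet", 4, 16))
  s2 <- network_spec("three_into_inception", depth = 3L, base_channels = 16L)
  expect_equal(n_parameters(s2), analytic_param_count("inception", 3, 16))
  expect_error(network_spec(n_classes = 4L), class = "inearseg_config_error")
})

test_that("augmentation operators behave as documented", {
  st <- fix_study()
  samp <- make_training_samples(st)[[1]]
  # null augmentation is the identity
  a0 <- augment_sample(samp, flip = FALSE, shift = c(0L, 0L), gain = 1)
  expect_equal(a0$triplet$main, samp$triplet$main)
  expect_identical(a0$label$labels, samp$label$labels)
  # flip (shift 0, gain 1) is an involution on images and label together
  a1 <- augment_sample(samp, flip = TRUE, shift = c(0L, 0L), gain = 1)
  a2 <- augment_sample(a1, flip = TRUE, shift = c(0L, 0L), gain = 1)
  expect_equal(a2$triplet$prev, samp$triplet$prev)
  expect_equal(a2$triplet$main, samp$triplet$main)
  expect_identical(a2$label$labels, samp$label$labels)
  expect_false(isTRUE(all.equal(a1$triplet$main, samp$triplet$main)))
  # gain scales images only
  a3 <- augment_sample(samp, flip = FALSE, shift = c(0L, 0L), gain = 1.5)
  expect_equal(a3$triplet$nxt, samp$triplet$nxt * 1.5)
  expect_identical(a3$label$labels, samp$label$labels)
  # shift moves images and label identically
  a4 <- augment_sample(samp, flip = FALSE, shift = c(3L, -2L), gain = 1)
  expect_equal(a4$triplet$main[10:100, 1:98],
               samp$triplet$main[7:97, 3:100])
  expect_equal(a4$label$labels[10:100, 1:98],
               samp$label$labels[7:97, 3:100])
  # fixed seed gives a byte-identical augmented stream
  set.seed(77); s1 <- lapply(1:5, function(i) augment_sample(samp))
  set.seed(77); s2 <- lapply(1:5, function(i) augment_sample(samp))
  expect_identical(s1, s2)
})

test_that("backpropagation matches central finite differences", {
  cn <- asNamespace("inearseg")
  set.seed(42)
  for (variant in 0:1) {
    depth <- 2L; base <- 4L; K <- 3L; ins <- 12L
    w <- cn$cnet_init_weights(variant, depth, base, K, ins, 7L)
    np <- length(w)
    x <- array(rnorm(ins * ins * 3), c(ins, ins, 3))
    y <- matrix(sample(0:2, ins * ins, TRUE), ins, ins)
    cwts <- c(1, 2, 3)
    loss_at <- function(wv)
      cn$cnet_train_batches(wv, numeric(np), numeric(np), 0L, variant,
                            depth, base, K, ins, list(x), list(y), 0.0,
                            cwts, 0.0, 1L, 1L)$losses[1]
    # with lr = 0 the weights stay put and Adam's first moment is 0.1 * grad
    r <- cn$cnet_train_batches(w, numeric(np), numeric(np), 0L, variant,
                               depth, base, K, ins, list(x), list(y), 0.0,
                               cwts, 0.0, 1L, 1L)
    g <- r$m / 0.1
    for (i in sample(np, 12)) {
      e <- 1e-5
      wp <- w; wp[i] <- wp[i] + e
      wm <- w; wm[i] <- wm[i] - e
      num <- (loss_at(wp) - loss_at(wm)) / (2 * e)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-4)
    }
  }
})

test_that("curriculum bookkeeping multiplies originals by the phase factor", {
  expect_equal(augmented_count(372, 14544), 5410368)
  expect_equal(augmented_count(1, 1), 1)
  expect_error(training_config(phase1_augmentation_factor = 0),
               class = "inearseg_config_error")
})

test_that("curriculum training hands phase-1 weights to phase 2 and is seeded", {
  st <- fix_study()
  samps <- make_training_samples(st)
  spec <- tiny_spec()
  cfg <- training_config(learning_rate = 1e-3, dropout = 0,
                         phase1_augmentation_factor = 2L,
                         phase2_augmentation_factor = 1L,
                         rng_seed = 9L, class_weights = c(1, 4, 4),
                         max_restarts = 0L)
  netA <- train_curriculum(samps, spec, cfg, init_seed = 4L)
  expect_true(netA$trained)
  expect_equal(netA$counters$phase1$n_augmented,
               2 * sum(vapply(samps, function(s)
                 s$annotation_mode == "selective", logical(1))))
  expect_equal(netA$counters$phase2$n_augmented, length(samps))
  # same seed and config: identical loss curve and weights
  netB <- train_curriculum(samps, spec, cfg, init_seed = 4L)
  expect_identical(netA$history$loss, netB$history$loss)
  expect_identical(netA$weights, netB$weights)
  # phase-1 training is unaffected by phase-2 settings: the hand-off weights
  # of a run with different phase-2 length are identical
  cfg2 <- cfg; cfg2$phase2_augmentation_factor <- 2L
  netC <- train_curriculum(samps, spec, cfg2, init_seed = 4L)
  expect_identical(netC$phase1_weights, netA$phase1_weights)
  # loss history covers both phases in order
  expect_identical(sort(unique(netA$history$phase)), c(1L, 2L))
  # training with no full samples is rejected
  sel_only <- Filter(function(s) s$annotation_mode == "selective", samps)
  expect_error(train_curriculum(sel_only, spec, cfg),
               class = "inearseg_training_error")
})

test_that("a small network can overfit a single phantom sample", {
  st <- fix_study()
  samps <- make_training_samples(st)
  sel <- Filter(function(s) s$annotation_mode == "selective", samps)[1]
  ful <- Filter(function(s) s$annotation_mode == "full", samps)[1]
  spec <- tiny_spec(depth = 3L, base = 8L)
  cfg <- training_config(learning_rate = 5e-3, dropout = 0,
                         phase1_augmentation_factor = 1L,
                         phase2_augmentation_factor = 1L,
                         phase1_epochs = 2L, phase2_epochs = 700L,
                         batch_size = 2L, rng_seed = 10L,
                         flip_probability = 0, shift_range_px = 0L,
                         intensity_gain_range = c(1, 1),
                         class_weights = c(1, 8, 8), max_restarts = 0L)
  net <- train_curriculum(c(sel, ful), spec, cfg, init_seed = 6L)
  h2 <- net$history[net$history$phase == 2L, ]
  expect_lt(tail(h2$loss, 1), 0.1)
  expect_lt(tail(h2$loss, 1), h2$loss[1])
  # prediction on the memorised sample recovers its own label almost exactly
  pred <- predict_patch(net, sel[[1]]$triplet)
  acc <- mean(pred$labels == sel[[1]]$label$labels)
  expect_gte(acc, 0.95)
  for (lab in 1:2)
    if (any(sel[[1]]$label$labels == lab))
      expect_gte(iou(sel[[1]]$label$labels == lab, pred$labels == lab), 0.9)
})
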