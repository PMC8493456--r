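#' Two-phase curriculum training configuration
#'
#' Defaults follow the reference training regime: Adam at learning rate 1e-5,
#' batch size 4, bottleneck dropout 0.4, a moderate augmentation factor of
#' 1584 for phase 1 (selectively annotated key slices only) and a high factor
#' of 14,544 for phase 2 (selective plus fully annotated stacks). Those
#' factors are bookkeeping multipliers: each original sample contributes
#' `factor` randomly augmented variants to the phase's training stream.
#' Desk-scale runs use much smaller factors and a larger learning rate; every
#' knob is an argument.
#'
#' @param learning_rate Adam step size.
#' @param batch_size samples per optimiser step.
#' @param dropout bottleneck dropout rate during training.
#' @param phase1_augmentation_factor,phase2_augmentation_factor augmented
#'   copies per original sample in each phase (>= 1).
#' @param phase1_epochs,phase2_epochs passes over each phase's augmented
#'   stream.
#' @param rng_seed integer; fixes augmentation order, augmentation draws and
#'   dropout, so a fixed seed reproduces the loss curve exactly.
#' @param flip_probability,shift_range_px,intensity_gain_range augmentation
#'   magnitudes, see [augment_sample()].
#' @param class_weights length-3 weights for the pixel-wise cross-entropy
#'   (background, cochlea, vestibule); organs are up-weighted by default to
#'   counter the residual background dominance inside a patch.
#' @param max_restarts maximum curriculum reinitialisations when organ-class
#'   collapse is detected (see [train_curriculum()]); 0 disables the check.
#' @param restart_threshold minimum per-class pixel recovery on the
#'   selective samples after training; below it the run is declared
#'   collapsed.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-5, batch_size = 4L,
                            dropout = 0.4,
                            phase1_augmentation_factor = 1584L,
                            phase2_augmentation_factor = 14544L,
                            phase1_epochs = 1L, phase2_epochs = 1L,
                            rng_seed = 1L, flip_probability = 0.5,
                            shift_range_px = 5L,
                            intensity_gain_range = c(0.8, 1.2),
                            class_weights = c(1, 4, 4),
                            max_restarts = 2L, restart_threshold = 0.2) {
  if (phase1_augmentation_factor < 1L || phase2_augmentation_factor < 1L)
    abort_inearseg("augmentation factors must be >= 1",
                   "inearseg_config_error")
  if (batch_size < 1L || phase1_epochs < 1L || phase2_epochs < 1L)
    abort_inearseg("batch size and epoch counts must be >= 1",
                   "inearseg_config_error")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 phase1_augmentation_factor = as.integer(phase1_augmentation_factor),
                 phase2_augmentation_factor = as.integer(phase2_augmentation_factor),
                 phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 rng_seed = as.integer(rng_seed),
                 flip_probability = flip_probability,
                 shift_range_px = as.integer(shift_range_px),
                 intensity_gain_range = intensity_gain_range,
                 class_weights = as.numeric(class_weights),
                 max_restarts = as.integer(max_restarts),
                 restart_threshold = restart_threshold),
            class = "training_config")
}

#' Augmented sample count of a training phase
#'
#' Pure bookkeeping: `n_original` annotated slices augmented `factor` times
#' yield `n_original * factor` training samples (372 originals at factor
#' 14,544 give 5,410,368).
#'
#' @param n_original number of original annotated slices.
#' @param factor augmentation factor.
#' @return The augmented sample count (double, to avoid integer overflow).
#' @export
augmented_count <- function(n_original, factor) {
  as.numeric(n_original) * as.numeric(factor)
}

#' Train a segmentation network with the two-phase curriculum
#'
#' Phase 1 optimises on selectively annotated samples only (key slices);
#' phase 2 continues from the phase-1 weights on the union of selective and
#' fully annotated samples. The loss is pixel-wise (optionally
#' class-weighted) categorical cross-entropy; each phase streams
#' `n_originals x factor` augmented samples per epoch in a seeded random
#' order.
#'
#' Because the two organ classes share intensity and differ mainly in shape,
#' short small-scale runs are bistable: some initialisations converge to a
#' merged-organ labelling in which every organ pixel takes one class. After
#' the curriculum finishes, the per-class pixel recovery is therefore probed
#' on the selective (training) samples; if any class recovers less than
#' `restart_threshold` of its pixels, the whole curriculum is restarted from
#' a fresh deterministic initialisation (up to `max_restarts` times). The
#' check uses training data only and is fully seeded, so runs remain
#' reproducible.
#'
#' @param samples list of [annotated_sample()]s containing at least one
#'   `selective` and one `full` sample.
#' @param spec a [network_spec()].
#' @param config a [training_config()].
#' @param init_seed seed for weight initialisation.
#' @param verbose print per-epoch progress.
#' @return A trained `inear_net` with `history` (data.frame of per-step
#'   losses), `counters` (per-phase original/augmented sample counts) and
#'   `phase1_weights` (the curriculum hand-off snapshot).
#' @export
train_curriculum <- function(samples, spec, config = training_config(),
                             init_seed = 1L, verbose = FALSE) {
  modes <- vapply(samples, function(s) s$annotation_mode, character(1))
  sel <- samples[modes == "selective"]
  if (length(sel) == 0L || sum(modes == "full") == 0L)
    abort_inearseg("need at least one selective and one full sample",
                   "inearseg_training_error")
  counters <- list(
    phase1 = list(n_original = length(sel),
                  factor = config$phase1_augmentation_factor,
                  n_augmented = augmented_count(
                    length(sel), config$phase1_augmentation_factor)),
    phase2 = list(n_original = length(samples),
                  factor = config$phase2_augmentation_factor,
                  n_augmented = augmented_count(
                    length(samples), config$phase2_augmentation_factor)))
  attempt <- 0L
  repeat {
    net <- build_network(spec, seed = init_seed + 1009L * attempt)
    set.seed(config$rng_seed + attempt)
    hist <- list()
    net <- run_phase(net, sel, config, config$phase1_augmentation_factor,
                     config$phase1_epochs, phase = 1L, hist, verbose)
    hist <- net$hist; net$hist <- NULL
    phase1_weights <- net$weights
    net <- run_phase(net, samples, config, config$phase2_augmentation_factor,
                     config$phase2_epochs, phase = 2L, hist, verbose)
    hist <- net$hist; net$hist <- NULL
    if (config$max_restarts == 0L) break
    rec <- class_recovery(net, sel)
    if (all(rec >= config$restart_threshold)) break
    if (attempt >= config$max_restarts) {
      warning(sprintf(
        "organ-class collapse persisted after %d reinitialisations (class recovery %.2f / %.2f)",
        attempt, rec[1], rec[2]), call. = FALSE)
      break
    }
    attempt <- attempt + 1L
    if (verbose)
      message(sprintf(
        "training collapsed (class recovery %.2f / %.2f); reinitialising (attempt %d)",
        rec[1], rec[2], attempt))
  }
  net$history <- do.call(rbind, hist)
  net$config <- config
  net$counters <- counters
  net$phase1_weights <- phase1_weights
  net$restarts <- attempt
  net$trained <- TRUE
  net
}

# fraction of each organ class's pixels recovered on (a subsample of) the
# selective training samples; collapsed runs sit near 0 for one class
class_recovery <- function(net, sel) {
  idx <- unique(round(seq(1, length(sel), length.out = min(40L, length(sel)))))
  tot <- c(0, 0); hit <- c(0, 0)
  for (s in sel[idx]) {
    pm <- predict_patch(net, s$triplet)
    for (k in 1:2) {
      tot[k] <- tot[k] + sum(s$label$labels == k)
      hit[k] <- hit[k] + sum(pm$labels == k & s$label$labels == k)
    }
  }
  ifelse(tot > 0, hit / tot, 1)
}

run_phase <- function(net, originals, config, factor, epochs, phase, hist,
                      verbose) {
  spec <- net$spec
  chunk <- max(config$batch_size, 32L)
  for (ep in seq_len(epochs)) {
    order <- sample(rep(seq_along(originals), factor))
    i <- 1L
    while (i <= length(order)) {
      idx <- order[i:min(length(order), i + chunk - 1L)]
      xs <- vector("list", length(idx)); ys <- xs
      for (j in seq_along(idx)) {
        aug <- augment_sample(originals[[idx[j]]],
                              flip_probability = config$flip_probability,
                              shift_range_px = config$shift_range_px,
                              intensity_gain_range = config$intensity_gain_range)
        xs[[j]] <- triplet_input(aug$triplet, spec$input_size)
        ys[[j]] <- aug$label$labels
      }
      res <- cnet_train_batches(
        net$weights, net$opt$m, net$opt$v, net$opt$t,
        variant_code(spec), spec$depth, spec$base_channels, spec$n_classes,
        spec$input_size, xs, ys, config$learning_rate, config$class_weights,
        config$dropout,
        seed = (config$rng_seed * 131L + net$opt$t) %% 2147483647L,
        batch_size = config$batch_size)
      net$weights <- res$weights
      net$opt <- list(m = res$m, v = res$v, t = res$t)
      hist[[length(hist) + 1L]] <-
        data.frame(phase = phase, epoch = ep,
                   step = res$t - length(res$losses) + seq_along(res$losses),
                   loss = res$losses)
      i <- i + chunk
    }
    if (verbose) {
      ep_loss <- mean(hist[[length(hist)]]$loss)
      message(sprintf("phase %d epoch %d: last-chunk mean loss %.4f",
                      phase, ep, ep_loss))
    }
  }
  net$hist <- hist
  net
}
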