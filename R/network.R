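#' Specify a three-slice-input segmentation network
#'
#' Both variants take the previous/main/next 100x100 MRC patches through three
#' encoder branches with independent weights; skip features and bottleneck
#' features are summed element-wise across branches before a single-stream
#' decoder produces a per-pixel 3-class probability map (background, cochlea,
#' vestibule).
#'
#' * `three_into_unet`: plain double-3x3-conv encoder blocks with max-pooling,
#'   mirrored decoder with 2x2 up-convolutions and summed-skip concatenation.
#' * `three_into_inception`: the encoder blocks are inception-style
#'   multi-branch units (parallel 1x1, 3x3 and stacked-3x3 paths concatenated);
#'   the truncation depth is the `depth` knob; the decoder is identical.
#'
#' @param variant `"three_into_unet"` or `"three_into_inception"`.
#' @param depth number of encoder levels (pooling steps), default 4.
#' @param base_channels channels at the first level; doubled per level.
#'   Must be divisible by 4 for the inception variant.
#' @param n_classes number of output classes; the organ contract fixes this
#'   at 3.
#' @param dropout_rate dropout applied to bottleneck features during training.
#' @param input_size patch side length (default 100).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(variant = c("three_into_unet", "three_into_inception"),
                         depth = 4L, base_channels = 16L, n_classes = 3L,
                         dropout_rate = 0.4, input_size = PATCH_SIZE) {
  variant <- match.arg(variant)
  if (n_classes != 3L)
    abort_inearseg("the organ contract requires n_classes == 3",
                   "inearseg_config_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_inearseg("dropout_rate must be in [0, 1)", "inearseg_config_error")
  if (depth < 1L)
    abort_inearseg("depth must be >= 1", "inearseg_config_error")
  if (variant == "three_into_inception" && base_channels %% 4L != 0L)
    abort_inearseg("inception variant needs base_channels divisible by 4",
                   "inearseg_config_error")
  structure(list(variant = variant, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 input_size = as.integer(input_size)),
            class = "network_spec")
}

variant_code <- function(spec) {
  match(spec$variant, c("three_into_unet", "three_into_inception")) - 1L
}

#' Number of trainable parameters of a network spec
#' @param spec a [network_spec()].
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(spec) {
  cnet_param_count(variant_code(spec), spec$depth, spec$base_channels,
                   spec$n_classes, spec$input_size)
}

#' Build (initialise) a segmentation network
#'
#' He-initialised weights, zero biases, fresh Adam state. The returned object
#' is the package's fitted-model class; [train_curriculum()] returns the same
#' class with trained weights and a loss history.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `inear_net` (also `inear_segmenter`).
#' @export
build_network <- function(spec, seed = 1L) {
  if (!inherits(spec, "network_spec"))
    abort_inearseg("spec must be a network_spec", "inearseg_config_error")
  w <- cnet_init_weights(variant_code(spec), spec$depth, spec$base_channels,
                         spec$n_classes, spec$input_size, as.integer(seed))
  structure(list(spec = spec, weights = w,
                 opt = list(m = numeric(length(w)), v = numeric(length(w)),
                            t = 0L),
                 history = NULL, config = NULL, counters = NULL,
                 trained = FALSE, init_seed = as.integer(seed)),
            class = c("inear_net", "inear_segmenter"))
}

#' Segment one patch triplet
#'
#' Generic over segmenter types: trained networks ([build_network()],
#' [train_curriculum()]) and the ground-truth oracle
#' ([gt_oracle_segmenter()]). Patches are mean-subtracted before the forward
#' pass; the per-pixel argmax of the class probabilities is returned.
#'
#' @param model a segmenter.
#' @param triplet a [extract_patch_triplet()] result.
#' @param ... passed to methods.
#' @return A [segmentation_mask()] for the main slice.
#' @export
predict_patch <- function(model, triplet, ...) UseMethod("predict_patch")

#' @export
predict_patch.inear_net <- function(model, triplet, ...) {
  probs <- patch_probabilities(model, triplet)
  lab <- apply(probs, c(1, 2), which.max) - 1L
  segmentation_mask(lab, triplet$side, triplet$main_slice_index)
}

#' Per-pixel class probabilities for one patch triplet
#' @param model an `inear_net`.
#' @param triplet a [extract_patch_triplet()] result.
#' @return `input_size x input_size x n_classes` array; each pixel sums to 1.
#' @export
patch_probabilities <- function(model, triplet) {
  s <- model$spec
  x <- triplet_input(triplet, s$input_size)
  cnet_predict(model$weights, variant_code(s), s$depth, s$base_channels,
               s$n_classes, s$input_size, x)
}

triplet_input <- function(triplet, size) {
  for (f in c("prev", "main", "nxt"))
    if (!identical(dim(triplet[[f]]), c(size, size)))
      abort_inearseg(sprintf("patch shape must be %dx%d", size, size),
                     "inearseg_shape_error")
  array(c(mean_subtract(triplet$prev), mean_subtract(triplet$main),
          mean_subtract(triplet$nxt)),
        dim = c(size, size, 3L))
}

#' @export
print.inear_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<inear_net> %s  depth %d, base %d channels, %s parameters\n",
              s$variant, s$depth, s$base_channels,
              format(n_parameters(s), big.mark = ",")))
  if (x$trained) {
    cat(sprintf("  trained: phase 1 %s samples (factor %d), phase 2 %s samples (factor %d)\n",
                format(x$counters$phase1$n_augmented, big.mark = ","),
                x$counters$phase1$factor,
                format(x$counters$phase2$n_augmented, big.mark = ","),
                x$counters$phase2$factor))
    cat(sprintf("  final training loss %.4g\n",
                utils::tail(x$history$loss, 1)))
  } else cat("  untrained (initialised weights)\n")
  invisible(x)
}

#' @export
summary.inear_net <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    for (ph in unique(h$phase))
      cat(sprintf("  phase %d: %d optimiser steps, loss %.4g -> %.4g\n",
                  ph, sum(h$phase == ph),
                  h$loss[h$phase == ph][1],
                  utils::tail(h$loss[h$phase == ph], 1)))
  }
  invisible(object)
}

#' @export
coef.inear_net <- function(object, ...) object$weights

#' @export
plot.inear_net <- function(x, ...) {
  if (is.null(x$history)) {
    warning("untrained network: no loss history to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::plot(x$history$loss, type = "l", xlab = "optimiser step",
                 ylab = "batch loss", main = "training loss", ...)
  invisible(x)
}

#' @export
predict.inear_net <- function(object, newdata, ...) {
  if (inherits(newdata, "patch_triplet"))
    return(predict_patch(object, newdata))
  if (inherits(newdata, "study_case"))
    return(segment_stack(object, newdata$mrc, newdata$ref_points))
  abort_inearseg("newdata must be a patch_triplet or study_case",
                 "inearseg_config_error")
}

#' Save / load network checkpoints as JSON text
#'
#' The checkpoint holds the architecture spec and the flat weight vector at
#' full precision, so a reloaded network reproduces predictions exactly.
#'
#' @param model an `inear_net`.
#' @param path output file (`.json` or `.json.gz`).
#' @return `path` invisibly; `load_network` returns the `inear_net`.
#' @export
save_network <- function(model, path) {
  jsonlite::write_json(
    list(spec = unclass(model$spec), weights = model$weights,
         trained = model$trained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(j$spec$variant, j$spec$depth, j$spec$base_channels,
                       j$spec$n_classes, j$spec$dropout_rate,
                       j$spec$input_size)
  net <- build_network(spec, seed = 1L)
  net$weights <- as.numeric(j$weights)
  net$trained <- isTRUE(j$trained)
  net
}
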