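#' Configuration of the bespoke block-style network
#'
#' The network is a narrow VGG-style stack: `n_blocks` repeated units, each
#' a 3x3 same-padded convolution (ReLU, L2 weight decay) followed by a 20%
#' dropout layer and a 2x2 ceil-mode max pool (pooling after each of the
#' first `n_blocks - 1` blocks only), with the filter count doubling per
#' block; then three fully connected ReLU layers, a 50% dropout layer, and
#' a softmax classification layer with `n_classes` outputs. With the
#' defaults (200x200 input, 7 blocks, 16 base filters) the final
#' convolutional layer has 1024 filters on a 4x4 feature map
#' (200 -> 100 -> 50 -> 25 -> 13 -> 7 -> 4 under ceil-mode pooling).
#'
#' @param input_side input image side in pixels (default 200).
#' @param n_blocks number of convolutional blocks (default 7).
#' @param base_filters filters of the first block; block `i` has
#'   `base_filters * 2^(i-1)` (default 16).
#' @param conv_dropout dropout rate between each convolution and pool
#'   (default 0.2).
#' @param head_dropout dropout rate before the classification layer
#'   (default 0.5).
#' @param fc_widths widths of the fully connected layers (default
#'   `c(1024, 2048, 2048)`).
#' @param n_classes number of output classes (default 2).
#' @param l2_lambda L2 weight-decay coefficient on all weights (default
#'   1e-4).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param batch_size mini-batch size (default 32).
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_side = 200L, n_blocks = 7L,
                         base_filters = 16L, conv_dropout = 0.2,
                         head_dropout = 0.5,
                         fc_widths = c(1024L, 2048L, 2048L),
                         n_classes = 2L, l2_lambda = 1e-4,
                         learning_rate = 1e-5, batch_size = 32L) {
  stopifnot(is_count(input_side, 8L), is_count(n_blocks, 1L),
            is_count(base_filters, 1L), is_count(n_classes, 2L),
            is_count(batch_size, 1L), all(fc_widths >= 1))
  if (conv_dropout < 0 || conv_dropout >= 1 || head_dropout < 0 ||
      head_dropout >= 1)
    stopf("dropout rates must be in [0, 1)")
  structure(list(input_side = as.integer(input_side),
                 n_blocks = as.integer(n_blocks),
                 base_filters = as.integer(base_filters),
                 conv_dropout = conv_dropout, head_dropout = head_dropout,
                 fc_widths = as.integer(fc_widths),
                 n_classes = as.integer(n_classes), l2_lambda = l2_lambda,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size)),
            class = "model_config")
}

new_layer <- function(kind, ...) c(list(kind = kind, trainable = TRUE),
                                   list(...))

#' Build the framework-neutral layer specification
#'
#' @param config a [model_config()].
#' @return An object of class `stagernet_spec`: an ordered list of layer
#'   descriptors with inferred output shapes and trainable flags, plus the
#'   originating config.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  layers <- list()
  side <- config$input_side
  ch <- 1L
  for (i in seq_len(config$n_blocks)) {
    filters <- as.integer(config$base_filters * 2^(i - 1))
    layers <- c(layers, list(
      new_layer("conv", filters = filters, in_channels = ch,
                out_shape = c(side, side, filters)),
      new_layer("relu", out_shape = c(side, side, filters)),
      new_layer("dropout", rate = config$conv_dropout,
                out_shape = c(side, side, filters))))
    ch <- filters
    if (i < config$n_blocks) {
      if (side <= 1L)
        stopf("shape underflow: spatial side is already %d before pooling block %d",
              side, i)
      side <- as.integer(ceiling(side / 2))
      layers <- c(layers, list(new_layer("maxpool",
                                         out_shape = c(side, side, ch))))
    }
  }
  feat <- side * side * ch
  layers <- c(layers, list(new_layer("flatten", out_shape = feat)))
  inu <- feat
  for (w in config$fc_widths) {
    layers <- c(layers, list(
      new_layer("dense", units = w, in_units = inu, out_shape = w),
      new_layer("relu", out_shape = w)))
    inu <- w
  }
  layers <- c(layers, list(
    new_layer("dropout", rate = config$head_dropout, out_shape = inu),
    new_layer("dense", units = config$n_classes, in_units = inu,
              out_shape = config$n_classes),
    new_layer("softmax", out_shape = config$n_classes)))
  structure(list(layers = layers, config = config), class = "stagernet_spec")
}

#' @export
print.stagernet_spec <- function(x, ...) {
  cat(sprintf("<stagernet_spec: %d layers, input %dx%d, %s parameters>\n",
              length(x$layers), x$config$input_side, x$config$input_side,
              format(count_params(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- switch(l$kind,
      conv = sprintf("3x3, %d filters", l$filters),
      dense = sprintf("%d units", l$units),
      dropout = sprintf("rate %.2f", l$rate), "")
    cat(sprintf("  %2d %-8s %-18s -> %s%s\n", i, l$kind, extra,
                paste(l$out_shape, collapse = "x"),
                if (l$trainable) "" else "  [frozen]"))
  }
  invisible(x)
}

#' Infer per-layer output shapes
#'
#' Recomputes the deterministic shape chain (same-padded convolutions
#' preserve the side; 2x2 pooling halves it with ceiling) and checks it
#' against the shapes stored in the spec.
#'
#' @param spec a [build_model()] spec.
#' @param input_side input side; defaults to the spec's configured side.
#' @return A list of per-layer output shapes.
#' @export
infer_shapes <- function(spec, input_side = NULL) {
  stopifnot(inherits(spec, "stagernet_spec"))
  side <- if (is.null(input_side)) spec$config$input_side else input_side
  shape <- c(side, side, 1L)
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    shape <- switch(l$kind,
      conv = {
        if (length(shape) != 3L || l$in_channels != shape[3L])
          stopf("inconsistent spec at layer %d (conv expects %d channels, gets %s)",
                i, l$in_channels, paste(shape, collapse = "x"))
        c(shape[1L], shape[2L], l$filters)
      },
      relu = shape,
      dropout = shape,
      maxpool = {
        if (length(shape) != 3L)
          stopf("inconsistent spec at layer %d (maxpool on flat input)", i)
        c(ceiling(shape[1L] / 2), ceiling(shape[2L] / 2), shape[3L])
      },
      flatten = prod(shape),
      dense = {
        if (length(shape) != 1L || l$in_units != shape)
          stopf("inconsistent spec at layer %d (dense expects %d inputs, gets %s)",
                i, l$in_units, paste(shape, collapse = "x"))
        l$units
      },
      softmax = shape,
      stopf("unknown layer kind '%s' at layer %d", l$kind, i))
    out[[i]] <- shape
  }
  out
}

#' Freeze layers for fine-tuning
#'
#' Sets the trainable flags of the spec. Frozen parameters are left
#' bit-identical by any subsequent training.
#'
#' @param spec a [build_model()] spec.
#' @param policy `"none"` (all trainable), `"all_convolutional"` (freeze
#'   every layer up to and including the flatten, so only the fully
#'   connected and classification layers train), or an integer `n` to
#'   freeze the first `n` layers.
#' @return The spec with updated trainable flags.
#' @export
freeze_layers <- function(spec, policy = "none") {
  stopifnot(inherits(spec, "stagernet_spec"))
  nl <- length(spec$layers)
  frozen <- if (is.numeric(policy)) {
    if (!is_count(policy, 0L) || policy > nl)
      stopf("first_n policy must be an integer in 0..%d", nl)
    seq_len(policy)
  } else {
    switch(match.arg(policy, c("none", "all_convolutional")),
      none = integer(0L),
      all_convolutional = seq_len(which(vapply(spec$layers, `[[`, "",
                                               "kind") == "flatten")[1L]))
  }
  for (i in seq_len(nl)) spec$layers[[i]]$trainable <- !(i %in% frozen)
  spec
}

#' Total parameter count of a spec
#'
#' A pure function of the configuration: stable across runs and
#' initializations.
#'
#' @param spec a [build_model()] spec (or a `stagernet_model`).
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  if (inherits(spec, "stagernet_model")) spec <- spec$spec
  sum(vapply(spec$layers, function(l) {
    switch(l$kind,
      conv = 9 * l$in_channels * l$filters + l$filters,
      dense = l$in_units * l$units + l$units,
      0)
  }, numeric(1L)))
}

#' Initialize network parameters
#'
#' Uniform variance-scaling initialization: weights are drawn from
#' `U(-sqrt(6/fan_in), +sqrt(6/fan_in))`; biases start at zero.
#'
#' @param spec a [build_model()] spec.
#' @param seed integer seed.
#' @return An object of class `stagernet_model` holding the spec and a
#'   parameter list, ready for training or prediction.
#' @export
init_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "stagernet_spec"))
  params <- with_seed(seed, lapply(spec$layers, function(l) {
    switch(l$kind,
      conv = {
        fan_in <- 9 * l$in_channels
        lim <- sqrt(6 / fan_in)
        list(W = matrix(runif(fan_in * l$filters, -lim, lim), fan_in,
                        l$filters),
             b = numeric(l$filters))
      },
      dense = {
        lim <- sqrt(6 / l$in_units)
        list(W = matrix(runif(l$in_units * l$units, -lim, lim), l$units,
                        l$in_units),
             b = numeric(l$units))
      },
      NULL)
  }))
  structure(list(spec = spec, params = params, class_names = NULL),
            class = "stagernet_model")
}

#' @export
print.stagernet_model <- function(x, ...) {
  cat(sprintf("<stagernet_model: %s parameters%s>\n",
              format(count_params(x$spec), big.mark = ","),
              if (is.null(x$class_names)) " (untrained)"
              else paste0("; classes: ",
                          paste(x$class_names, collapse = ", "))))
  invisible(x)
}

#' Serialize a model spec to JSON
#'
#' @param spec a [build_model()] spec.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(list(config = unclass(spec$config),
                            layers = spec$layers),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
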