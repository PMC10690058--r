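# Shared fixtures: everything is generated in code, nothing is read from
# disk except files the tests themselves write to tempdir().

# A small two-class dataset of synthetic embryo-like images.
tiny_dataset <- function(n_per_class = 4L, side = 32L, difficulty = 0,
                         nuisance = "none", seed = 7L, ...) {
  generate_dataset(synthetic_config(n_per_class = n_per_class,
                                    image_side = side,
                                    difficulty = difficulty,
                                    nuisance = nuisance, seed = seed, ...))
}

# A bare labelled dataset of deterministic gradient images, ids "a1".."bN":
# class "a" is dark, class "b" bright -- trivially separable.
toy_separable_dataset <- function(n_per_class = 6L, side = 16L) {
  mk <- function(lab, i, level) {
    px <- matrix(level, side, side) +
      outer(seq_len(side), seq_len(side), function(r, c) (r + c) / (40 * side))
    labelled_image(clamp01ish(px), lab, paste0(lab, i))
  }
  img_dataset(c(lapply(seq_len(n_per_class), function(i) mk("a", i, 0.2)),
                lapply(seq_len(n_per_class), function(i) mk("b", i, 0.7))))
}

clamp01ish <- function(x) pmin(pmax(x, 0), 1)

# Tiny model configuration that trains in seconds.
tiny_model_config <- function(side = 16L, n_blocks = 2L, ...) {
  model_config(input_side = side, n_blocks = n_blocks, base_filters = 2L,
               fc_widths = c(8L), conv_dropout = 0, head_dropout = 0,
               learning_rate = 1e-2, batch_size = 8L, ...)
}

# Independent brute-force early-stopping oracle: simulate the rule epoch by
# epoch, literally tracking "epochs since the last strict improvement".
brute_force_early_stop <- function(history, patience, min_improvement) {
  best <- -Inf
  since <- 0L
  stopped_at <- NA_integer_
  for (t in seq_along(history)) {
    acc <- history[t]
    if (acc > best + min_improvement) since <- 0L else since <- since + 1L
    if (acc > best) best <- acc
    if (since >= patience) {
      stopped_at <- t
      break
    }
  }
  list(stop = !is.na(stopped_at), stopped_at = stopped_at,
       best_epoch = which.max(history))
}

# A hand-built linear model: flatten -> dense(2), fixed weights.
linear_model <- function(side, W, b = c(0, 0)) {
  cfg <- model_config(input_side = max(side, 8L), n_blocks = 1L,
                      base_filters = 1L, fc_widths = 4L, n_classes = 2L)
  feat <- side * side
  layers <- list(
    stagernet:::new_layer("flatten", out_shape = feat),
    stagernet:::new_layer("dense", units = 2L, in_units = feat,
                          out_shape = 2L),
    stagernet:::new_layer("softmax", out_shape = 2L))
  spec <- structure(list(layers = layers, config = cfg),
                    class = "stagernet_spec")
  m <- init_model(spec, seed = 1L)
  m$params[[2L]]$W <- W
  m$params[[2L]]$b <- b
  m
}
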