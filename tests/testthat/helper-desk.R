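# Desk-scale end-to-end pipeline runs shared by the acceptance tests: a
# reduced network (64x64 input, 4 blocks, 4 base filters) trained on one
# cross-validation fold of a synthetic dataset under the 36-rotation
# baseline regime.

desk_model_config <- function(...) {
  model_config(input_side = 64L, n_blocks = 4L, base_filters = 4L,
               fc_widths = c(64L, 64L), learning_rate = 1e-3,
               batch_size = 32L, ...)
}

desk_pipeline_run <- function(difficulty, seed, n_per_class = 30L,
                              nuisance = "moderate", flip = FALSE,
                              confound = FALSE, max_epochs = 25L,
                              patience = 6L, k = 5L) {
  cfg <- synthetic_config(n_per_class = n_per_class, image_side = 64L,
                          difficulty = difficulty, nuisance = nuisance,
                          confound_orientation = confound, seed = seed)
  ds <- preprocess_dataset(generate_dataset(cfg), 64L)
  plan <- split_plan(ds, 0.2, k, seed)
  reg <- augmentation_regime("single", flip = flip, seed = seed)
  fs <- assemble_fold(ds, plan, 1L, reg)
  fr <- train_fold(build_model(desk_model_config()), fs$train, fs$val,
                   train_config(max_epochs = max_epochs,
                                patience = patience, seed = seed))
  list(cfg = cfg, dataset = ds, plan = plan, fold = fr, model = fr$model,
       test_accuracy = evaluate_test(fr$model, test_set(ds, plan))$accuracy)
}

# Accuracy on a freshly generated balanced pool from the same generating
# distribution (never seen in training), for low-variance estimates.
fresh_pool_accuracy <- function(model, cfg, n_per_class = 50L, seed = 777L,
                                flip_images = FALSE) {
  cfg$n_per_class <- as.integer(n_per_class)
  cfg$seed <- as.integer(seed)
  ds <- preprocess_dataset(generate_dataset(cfg), cfg$image_side)
  if (flip_images)
    ds$images <- lapply(ds$images, function(im) {
      im$pixels <- hflip(im$pixels)
      im
    })
  evaluate_test(model, ds)$accuracy
}
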