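test_that("the early-stopping rule matches its specification on canonical cases", {
  # flat history: epoch 1 improves (from -Inf), then 10 stale epochs
  flat <- rep(0.5, 11L)
  es <- early_stop_decision(flat, patience = 10L, min_improvement = 1e-4)
  expect_true(es$stop)
  expect_identical(es$best_epoch, 1L)
  expect_false(early_stop_decision(flat[1:10], 10L, 1e-4)$stop)
  # strictly increasing by more than the threshold never stops
  inc <- 0.5 + (1:400) * 0.001
  expect_false(early_stop_decision(inc, 10L, 1e-4)$stop)
  # an improvement of exactly min_improvement does NOT reset the counter
  # (binary-exact values so the strict comparison is tested, not rounding)
  boundary <- c(0.5, 0.75, 1.0, 1.25)
  expect_true(early_stop_decision(boundary, 3L, 0.25)$stop)
  # but strictly more does
  expect_false(early_stop_decision(c(0.5, 1.0, 1.5, 2.0), 3L, 0.25)$stop)
  expect_error(early_stop_decision(numeric(0L), 10L, 1e-4), "empty")
})

test_that("the early-stopping rule agrees with brute-force simulation on random streams", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(3:40, 1L)
    hist <- round(cumsum(rnorm(n, 0.002, 0.05)) + 0.5, 3L)
    patience <- sample(2:8, 1L)
    thr <- sample(c(0, 1e-4, 1e-2), 1L)
    # feed the rule epoch by epoch exactly as the training loop does
    stopped_at <- NA_integer_
    for (t in seq_len(n)) {
      if (early_stop_decision(hist[seq_len(t)], patience, thr)$stop) {
        stopped_at <- t
        break
      }
    }
    oracle <- brute_force_early_stop(hist, patience, thr)
    expect_identical(!is.na(stopped_at), oracle$stop)
    expect_identical(early_stop_decision(hist, patience, thr)$best_epoch,
                     oracle$best_epoch)
  }
})

test_that("training learns a separable toy problem and reports a consistent history", {
  ds <- toy_separable_dataset(6L, side = 16L)
  plan <- split_plan(ds, 0.2, k = 2L, seed = 1L)
  reg <- augmentation_regime("single", n_angles = 4L, step = 90, seed = 1L)
  fs <- assemble_fold(ds, plan, 1L, reg)
  spec <- build_model(tiny_model_config(side = 16L))
  fr <- train_fold(spec, fs$train, fs$val, train_config(max_epochs = 30L,
                                                        patience = 5L,
                                                        seed = 2L))
  expect_gte(fr$best_val_accuracy, 0.9)
  expect_identical(fr$best_val_accuracy, max(fr$epoch_history$val_accuracy))
  expect_identical(fr$epoch_history$val_accuracy[fr$best_epoch],
                   fr$best_val_accuracy)
  expect_lte(nrow(fr$epoch_history), 30L)
  # restored parameters reproduce the best epoch's validation accuracy
  va <- stagernet:::dataset_to_array(fs$val, fr$model$class_names)
  acc <- mean(max.col(t(stagernet:::net_predict_probs(fr$model, va$x)),
                      ties.method = "first") == va$y)
  expect_equal(acc, fr$best_val_accuracy)
})

test_that("identical seeds give identical training histories", {
  ds <- toy_separable_dataset(4L, side = 16L)
  plan <- split_plan(ds, 0.25, k = 2L, seed = 3L)
  reg <- augmentation_regime("single", n_angles = 2L, step = 180, seed = 3L)
  fs <- assemble_fold(ds, plan, 1L, reg)
  spec <- build_model(tiny_model_config(side = 16L))
  tc <- train_config(max_epochs = 4L, patience = 2L, seed = 7L)
  a <- train_fold(spec, fs$train, fs$val, tc)
  b <- train_fold(spec, fs$train, fs$val, tc)
  expect_identical(a$epoch_history, b$epoch_history)
  expect_identical(a$model$params, b$model$params)
})

test_that("frozen layers stay bit-identical through training", {
  ds <- toy_separable_dataset(4L, side = 16L)
  plan <- split_plan(ds, 0.25, k = 2L, seed = 4L)
  reg <- augmentation_regime("single", n_angles = 2L, step = 180, seed = 4L)
  fs <- assemble_fold(ds, plan, 1L, reg)
  spec <- freeze_layers(build_model(tiny_model_config(side = 16L)),
                        "all_convolutional")
  init <- init_model(spec, seed = 5L)
  fr <- train_fold(spec, fs$train, fs$val,
                   train_config(max_epochs = 3L, patience = 2L, seed = 5L),
                   init = init)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  conv_idx <- which(kinds == "conv")
  dense_idx <- which(kinds == "dense")
  for (i in conv_idx)
    expect_identical(fr$model$params[[i]], init$params[[i]])
  # the unfrozen head did move
  expect_false(identical(fr$model$params[[dense_idx[1L]]],
                         init$params[[dense_idx[1L]]]))
})

test_that("test evaluation counts argmax agreement and rejects bad inputs", {
  ds <- toy_separable_dataset(3L, side = 16L)
  # a constant model predicting class "a" via a huge bias
  m <- linear_model(16L, matrix(0, 2L, 256L), b = c(10, 0))
  m$class_names <- c("a", "b")
  ev <- evaluate_test(m, ds)
  expect_equal(ev$accuracy, 0.5)  # 3 of 6 are class "a"
  expect_identical(unique(ev$predictions$predicted), "a")
  # on a 14 + 17 split, the constant model scores 14/31
  ds2 <- img_dataset(c(
    lapply(1:14, function(i)
      labelled_image(matrix(runif(256), 16L), "a", paste0("a", i))),
    lapply(1:17, function(i)
      labelled_image(matrix(runif(256), 16L), "b", paste0("b", i)))))
  expect_equal(evaluate_test(m, ds2)$accuracy, 14 / 31)
  aug <- ds
  aug$images[[1L]]$transform_chain <- list(list(name = "rotate", angle = 10))
  expect_error(evaluate_test(m, aug), "unaugmented")
  expect_error(evaluate_test(m, img_dataset(list())), "empty")
})

test_that("cross-validation aggregates fold accuracies exactly", {
  ds <- toy_separable_dataset(5L, side = 16L)
  plan <- split_plan(ds, 0.2, k = 2L, seed = 6L)
  reg <- augmentation_regime("single", n_angles = 2L, step = 180, seed = 6L)
  cv <- run_cross_validation(ds, plan, reg, tiny_model_config(side = 16L),
                             train_config(max_epochs = 8L, patience = 3L,
                                          seed = 6L))
  expect_length(cv$fold_results, 2L)
  expect_identical(cv$mean_val_accuracy, mean(cv$val_accuracies))
  expect_identical(cv$sd_val_accuracy, sd(cv$val_accuracies))
  expect_identical(cv$best_fold, which.max(cv$val_accuracies))
  expect_identical(cv$val_accuracies[cv$best_fold],
                   max(cv$val_accuracies))
  expect_true(cv$test_accuracy >= 0 && cv$test_accuracy <= 1)
  # every non-test source validates in exactly one fold
  expect_setequal(unlist(plan$folds),
                  setdiff(unique(dataset_ids(ds)), plan$test_ids))
})

test_that("fine-tuning under a full freeze preserves the convolutional filters", {
  ds <- toy_separable_dataset(5L, side = 16L)
  plan <- split_plan(ds, 0.2, k = 2L, seed = 8L)
  reg <- augmentation_regime("single", n_angles = 2L, step = 180, seed = 8L)
  src <- run_cross_validation(ds, plan, reg, tiny_model_config(side = 16L),
                              train_config(max_epochs = 3L, patience = 2L,
                                           seed = 8L))
  ds2 <- toy_separable_dataset(5L, side = 16L)
  ft <- fine_tune(src$model, ds2, "all_convolutional", reg,
                  train_config(max_epochs = 3L, patience = 2L, seed = 9L),
                  k = 2L)
  kinds <- vapply(src$model$spec$layers, `[[`, "", "kind")
  for (i in which(kinds == "conv"))
    expect_identical(ft$model$params[[i]], src$model$params[[i]])
})
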