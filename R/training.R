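#' Training configuration
#'
#' Mini-batch training with Adam, early stopping and best-weight
#' restoration. Training halts once `patience` consecutive epochs have
#' each failed to exceed the running-best validation accuracy by strictly
#' more than `min_improvement` (default 0.0001, i.e. 0.01%), and the
#' parameters of the best epoch are restored before the model is returned.
#'
#' @param max_epochs epoch cap (default 500).
#' @param patience epochs without improvement before stopping (default 10).
#' @param min_improvement minimum validation-accuracy improvement that
#'   resets the patience counter; strictly-greater comparison (default
#'   1e-4).
#' @param restore_best restore the best-epoch parameters (default `TRUE`).
#' @param seed master seed for initialization, batch shuffling and dropout.
#' @param batch_size mini-batch size; `NULL` defers to the model config.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 500L, patience = 10L,
                         min_improvement = 1e-4, restore_best = TRUE,
                         seed = 1L, batch_size = NULL) {
  stopifnot(is_count(max_epochs, 1L), is_count(patience, 1L),
            patience < max_epochs, min_improvement >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_improvement = min_improvement,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed),
                 batch_size = if (!is.null(batch_size))
                   as.integer(batch_size)),
            class = "train_config")
}

#' Early-stopping decision rule
#'
#' Stop is signalled exactly when the last `patience` epochs each failed
#' to exceed the running-best validation accuracy by strictly more than
#' `min_improvement`; an epoch improving by exactly `min_improvement` does
#' not reset the counter. The best epoch is the earliest argmax of the
#' history.
#'
#' @param val_accuracy_history numeric vector of per-epoch validation
#'   accuracies (non-empty).
#' @param patience patience in epochs.
#' @param min_improvement strict improvement threshold.
#' @return A list with logical `stop` and integer `best_epoch`.
#' @export
early_stop_decision <- function(val_accuracy_history, patience = 10L,
                                min_improvement = 1e-4) {
  n <- length(val_accuracy_history)
  if (n == 0L) stopf("empty validation history")
  improved <- logical(n)
  best <- -Inf
  for (t in seq_len(n)) {
    improved[t] <- val_accuracy_history[t] > best + min_improvement
    best <- max(best, val_accuracy_history[t])
  }
  stop <- n >= patience && !any(improved[(n - patience + 1L):n])
  list(stop = stop, best_epoch = which.max(val_accuracy_history))
}

#' Train the network on one fold
#'
#' Optimizes the spec's trainable parameters by mini-batch Adam on the
#' (augmented) training set, monitoring accuracy on the (augmented)
#' validation set after every epoch, with early stopping and best-weight
#' restoration per the train config. Layers frozen in the spec are left
#' bit-identical.
#'
#' @param spec a [build_model()] spec (possibly with frozen layers).
#' @param train_set,val_set [img_dataset()]s with disjoint source ids.
#' @param config a [train_config()].
#' @param init optional `stagernet_model` supplying starting parameters
#'   (for fine-tuning); by default parameters are freshly initialized from
#'   the config seed.
#' @param class_names optional fixed class ordering; defaults to the
#'   sorted labels of the training set.
#' @param fold_index bookkeeping index stored in the result.
#' @return An object of class `stagernet_fold`: the trained model plus the
#'   epoch history (`epoch`, `train_loss`, `train_accuracy`,
#'   `val_accuracy`), `best_epoch` and `best_val_accuracy`.
#' @export
train_fold <- function(spec, train_set, val_set, config = train_config(),
                       init = NULL, class_names = NULL, fold_index = 1L) {
  stopifnot(inherits(spec, "stagernet_spec"),
            inherits(config, "train_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    stopf("empty training or validation set")
  overlap <- intersect(unique(dataset_ids(train_set)),
                       unique(dataset_ids(val_set)))
  if (length(overlap) > 0L)
    stopf("train/validation source ids overlap: %s",
          paste(head(overlap, 3L), collapse = ", "))
  if (is.null(class_names))
    class_names <- sort(unique(c(dataset_labels(train_set),
                                 dataset_labels(val_set))))
  tr <- dataset_to_array(train_set, class_names)
  va <- dataset_to_array(val_set, class_names)
  bs <- config$batch_size %||% spec$config$batch_size
  lr <- spec$config$learning_rate
  n <- dim(tr$x)[4L]

  with_seed(config$seed, {
    model <- if (is.null(init)) init_model(spec, seed = sample.int(1e9, 1L))
    else {
      m <- init
      m$spec <- spec
      m
    }
    opt <- adam_init(model)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_accuracy = numeric(), val_accuracy = numeric())
    best_params <- model$params
    best_acc <- -Inf
    step <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (s in seq(1L, n, by = bs)) {
        idx <- perm[s:min(s + bs - 1L, n)]
        lg <- net_loss_grads(model, tr$x[, , , idx, drop = FALSE], tr$y[idx])
        step <- step + 1L
        upd <- adam_step(model, lg$grads, opt, step, lr)
        model <- upd$model
        opt <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_correct <- ep_correct + lg$accuracy * length(idx)
      }
      val_acc <- mean(max.col(t(net_predict_probs(model, va$x)),
                              ties.method = "first") == va$y)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                     train_accuracy = ep_correct / n,
                                     val_accuracy = val_acc))
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_params <- model$params
      }
      es <- early_stop_decision(hist$val_accuracy, config$patience,
                                config$min_improvement)
      if (es$stop) break
    }
    if (config$restore_best) model$params <- best_params
    model$class_names <- class_names
    es <- early_stop_decision(hist$val_accuracy, config$patience,
                              config$min_improvement)
    structure(list(fold_index = fold_index, model = model,
                   epoch_history = hist, best_epoch = es$best_epoch,
                   best_val_accuracy = max(hist$val_accuracy)),
              class = "stagernet_fold")
  })
}

#' @export
print.stagernet_fold <- function(x, ...) {
  cat(sprintf(
    "<stagernet_fold %d: %d epochs, best val accuracy %.3f at epoch %d>\n",
    x$fold_index, nrow(x$epoch_history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' Evaluate a trained model on an unaugmented test set
#'
#' @param model a trained `stagernet_model`.
#' @param test_set an [img_dataset()] of unaugmented images.
#' @return A list with `accuracy` and a `predictions` data frame
#'   (`source_id`, `label`, `predicted`, one probability column per class).
#' @export
evaluate_test <- function(model, test_set) {
  if (length(test_set) == 0L) stopf("empty test set")
  augmented <- any(lengths(lapply(test_set$images, `[[`,
                                  "transform_chain")) > 0L)
  if (augmented) stopf("test set must be unaugmented")
  cn <- model$class_names %||% sort(unique(dataset_labels(test_set)))
  da <- dataset_to_array(test_set, cn)
  P <- t(net_predict_probs(model, da$x))
  pred_idx <- max.col(P, ties.method = "first")
  preds <- data.frame(source_id = dataset_ids(test_set),
                      label = dataset_labels(test_set),
                      predicted = cn[pred_idx], stringsAsFactors = FALSE)
  colnames(P) <- paste0("prob_", cn)
  list(accuracy = mean(pred_idx == da$y), predictions = cbind(preds, P))
}

#' Cross-validated training of the network
#'
#' Trains one freshly initialized model per fold (fold-indexed seeds
#' derived from the master seed), aggregates the mean and sample (n-1)
#' standard deviation of the best per-fold validation accuracies, and
#' evaluates the highest-validation-accuracy model on the untouched,
#' unaugmented test set.
#'
#' @param dataset preprocessed [img_dataset()] of originals.
#' @param plan a [split_plan()].
#' @param regime an [augmentation_regime()].
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param spec optional pre-built (e.g. partially frozen) spec; defaults to
#'   `build_model(mconfig)`.
#' @param init optional warm-start `stagernet_model` passed to every fold
#'   (used by [fine_tune()]).
#' @param folds which fold indices to run (default all; a subset is useful
#'   for quick experiments).
#' @return An object of class `stagernet_cv` with per-fold results, the
#'   aggregate statistics, the selected model and its test-set evaluation.
#' @export
run_cross_validation <- function(dataset, plan, regime, mconfig,
                                 tconfig = train_config(), spec = NULL,
                                 init = NULL, folds = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(spec)) spec <- build_model(mconfig)
  folds <- folds %||% seq_len(plan$k)
  class_names <- sort(unique(dataset_labels(dataset)))
  fold_seeds <- derive_seeds(tconfig$seed, plan$k)
  results <- lapply(folds, function(i) {
    fs <- assemble_fold(dataset, plan, i, regime)
    fc <- tconfig
    fc$seed <- fold_seeds[i]
    train_fold(spec, fs$train, fs$val, fc, init = init,
               class_names = class_names, fold_index = i)
  })
  accs <- vapply(results, `[[`, numeric(1L), "best_val_accuracy")
  best <- which.max(accs)
  test_eval <- evaluate_test(results[[best]]$model, test_set(dataset, plan))
  structure(list(fold_results = results, val_accuracies = accs,
                 mean_val_accuracy = mean(accs),
                 sd_val_accuracy = if (length(accs) > 1L) sd(accs) else NA_real_,
                 best_fold = folds[best], model = results[[best]]$model,
                 test_accuracy = test_eval$accuracy,
                 test_predictions = test_eval$predictions,
                 class_names = class_names),
            class = "stagernet_cv")
}

#' @export
print.stagernet_cv <- function(x, ...) {
  cat(sprintf(
    "<stagernet_cv: %d fold(s); val accuracy %.3f +/- %.3f; test accuracy %.3f (best fold %d)>\n",
    length(x$fold_results), x$mean_val_accuracy, x$sd_val_accuracy,
    x$test_accuracy, x$best_fold))
  invisible(x)
}

#' @export
summary.stagernet_cv <- function(object, ...) {
  cat("Cross-validated network training\n")
  cat(sprintf("  classes: %s\n", paste(object$class_names, collapse = ", ")))
  for (r in object$fold_results)
    cat(sprintf("  fold %2d: best val accuracy %.3f (epoch %d of %d)\n",
                r$fold_index, r$best_val_accuracy, r$best_epoch,
                nrow(r$epoch_history)))
  cat(sprintf("  mean +/- sd (n-1): %.3f +/- %.3f\n",
              object$mean_val_accuracy, object$sd_val_accuracy))
  cat(sprintf("  independent test accuracy (fold %d model): %.3f\n",
              object$best_fold, object$test_accuracy))
  invisible(object)
}

#' Fine-tune a trained model on a second dataset
#'
#' Cross-validation on the new dataset starting from the source model's
#' parameters under a freeze policy: with `"all_convolutional"` the learnt
#' convolutional feature extractors are held bit-identical and only the
#' fully connected head retrains (the head is freshly re-initialized by
#' default). For orientation-confounded data the regime's baseline should
#' include horizontal flips.
#'
#' @param source_model a trained `stagernet_model`.
#' @param new_dataset preprocessed [img_dataset()] with the same image
#'   geometry and class count.
#' @param freeze_policy passed to [freeze_layers()].
#' @param regime an [augmentation_regime()].
#' @param tconfig a [train_config()].
#' @param plan optional [split_plan()]; by default a fresh plan with
#'   `test_fraction` and `k`.
#' @param test_fraction,k used when `plan` is `NULL`.
#' @param reinit_head freshly initialize the trainable layers before
#'   fine-tuning (default `TRUE`).
#' @param folds which folds to run (default all).
#' @return A `stagernet_cv` object.
#' @export
fine_tune <- function(source_model, new_dataset,
                      freeze_policy = "all_convolutional", regime,
                      tconfig = train_config(), plan = NULL,
                      test_fraction = 0.2, k = 10L, reinit_head = TRUE,
                      folds = NULL) {
  stopifnot(inherits(source_model, "stagernet_model"))
  spec <- freeze_layers(source_model$spec, freeze_policy)
  d <- dim(new_dataset$images[[1L]]$pixels)
  if (d[1L] != spec$config$input_side)
    stopf("new dataset geometry %dx%d does not match model input %dx%d",
          d[1L], d[2L], spec$config$input_side, spec$config$input_side)
  if (is.null(plan))
    plan <- split_plan(new_dataset, test_fraction, k, seed = tconfig$seed)
  warm <- source_model
  warm$spec <- spec
  if (reinit_head) {
    fresh <- with_seed(tconfig$seed, init_model(spec,
                                                seed = sample.int(1e9, 1L)))
    for (i in seq_along(spec$layers))
      if (spec$layers[[i]]$trainable && !is.null(warm$params[[i]]))
        warm$params[[i]] <- fresh$params[[i]]
  }
  run_cross_validation(new_dataset, plan, regime, spec$config, tconfig,
                       spec = spec, init = warm, folds = folds)
}
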