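#' Assemble and validate an experiment configuration
#'
#' One declarative object driving the whole pipeline: data source
#' (manifest CSV or synthetic generator), preprocessing, augmentation
#' regime, split settings, model and training configuration, saliency
#' settings, and the output directory. Defaults are materialized at load
#' time so the stored copy of a config fully describes the run. Accepts a
#' YAML file path or a nested list with the same structure.
#'
#' @param x YAML file path or nested list. Recognized top-level fields:
#'   `data` (either `manifest:` path or `synthetic:` arguments for
#'   [synthetic_config()]), `preprocess` (`side`, `equalize_first`),
#'   `regime` (arguments for [augmentation_regime()]; extras as a list of
#'   `name` + parameters), `split` (`test_fraction`, `k`, `seed`), `model`
#'   (arguments for [model_config()]), `train` (arguments for
#'   [train_config()]), `saliency` (`n_samples`, `noise_sigma`,
#'   `filter_quantile`), `out_dir`.
#' @return An object of class `experiment_config` with all defaults
#'   materialized.
#' @export
experiment_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  data <- x$data %||% list(synthetic = list())
  if (!is.null(data$manifest) && !file.exists(data$manifest))
    stopf("manifest not found: %s", data$manifest)
  if (is.null(data$manifest))
    data$synthetic <- do.call(synthetic_config,
                              data$synthetic %||% list())
  pre <- utils::modifyList(list(side = NULL, equalize_first = FALSE),
                           x$preprocess %||% list())
  reg <- x$regime %||% list()
  if (!is.null(reg$extras))
    reg$extras <- lapply(reg$extras, function(e)
      do.call(transform_spec, e))
  regime <- do.call(augmentation_regime, reg)
  split <- utils::modifyList(list(test_fraction = 0.2, k = 10L, seed = 1L),
                             x$split %||% list())
  if (split$test_fraction <= 0 || split$test_fraction >= 1)
    stopf("an independent test set is mandatory: test_fraction must be in (0, 1)")
  mconfig <- do.call(model_config, x$model %||% list())
  tconfig <- do.call(train_config, x$train %||% list())
  sal <- utils::modifyList(list(n_samples = 20L, noise_sigma = 0.1,
                                filter_quantile = 0.75),
                           x$saliency %||% list())
  structure(list(data = data, preprocess = pre, regime = regime,
                 split = split, model = mconfig, train = tconfig,
                 saliency = sal, out_dir = x$out_dir %||% NULL),
            class = "experiment_config")
}

#' Run a full experiment from a configuration
#'
#' Executes preprocess, split, per-fold augmentation, cross-validated
#' training, test evaluation, and saliency map generation on the test set,
#' then (if `out_dir` is set) writes the cross-validation summary JSON,
#' per-fold epoch histories CSV, test predictions CSV, saliency CSVs and a
#' provenance record (config, seeds, package version). Two runs from the
#' same config produce identical summaries.
#'
#' @param config an [experiment_config()] (or YAML path / list coercible
#'   to one).
#' @param folds optional subset of folds (default all).
#' @return A list with the dataset, plan, `stagernet_cv` result, saliency
#'   maps of the test images, and the output directory (if written).
#' @export
run_experiment <- function(config, folds = NULL) {
  if (!inherits(config, "experiment_config"))
    config <- experiment_config(config)
  dataset <- if (!is.null(config$data$manifest))
    load_manifest(config$data$manifest)
  else generate_dataset(config$data$synthetic)
  side <- config$preprocess$side %||% config$model$input_side
  if (side != config$model$input_side)
    stopf("preprocess side (%d) must match the model input side (%d)",
          side, config$model$input_side)
  dataset <- preprocess_dataset(dataset, side,
                                config$preprocess$equalize_first)
  plan <- split_plan(dataset, config$split$test_fraction, config$split$k,
                     config$split$seed)
  cv <- run_cross_validation(dataset, plan, config$regime, config$model,
                             config$train, folds = folds)
  tst <- test_set(dataset, plan)
  maps <- lapply(seq_along(tst$images), function(i)
    smoothgrad(cv$model, tst$images[[i]]$pixels,
               n_samples = config$saliency$n_samples,
               noise_sigma = config$saliency$noise_sigma,
               seed = config$split$seed + i))
  names(maps) <- dataset_ids(tst)
  out <- list(dataset = dataset, plan = plan, cv = cv, saliency = maps,
              out_dir = config$out_dir)
  if (!is.null(config$out_dir)) write_experiment(out, config)
  out
}

write_experiment <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cv <- result$cv
  summary_json <- list(
    mean_val_accuracy = cv$mean_val_accuracy,
    sd_val_accuracy = cv$sd_val_accuracy,
    val_accuracies = cv$val_accuracies,
    best_fold = cv$best_fold,
    test_accuracy = cv$test_accuracy,
    class_names = cv$class_names)
  jsonlite::write_json(summary_json, file.path(config$out_dir,
                                               "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  hist <- do.call(rbind, lapply(cv$fold_results, function(r)
    cbind(fold = r$fold_index, r$epoch_history)))
  write.csv(hist, file.path(config$out_dir, "epoch_history.csv"),
            row.names = FALSE)
  write.csv(cv$test_predictions,
            file.path(config$out_dir, "test_predictions.csv"),
            row.names = FALSE)
  sal_dir <- file.path(config$out_dir, "saliency")
  dir.create(sal_dir, showWarnings = FALSE)
  for (id in names(result$saliency))
    write_saliency(result$saliency[[id]],
                   csv_path = file.path(sal_dir, paste0(id, ".csv")))
  write_split_plan(result$plan, file.path(config$out_dir, "split_plan.json"))
  prov <- list(package_version = as.character(utils::packageVersion("stagernet")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               seeds = list(split = config$split$seed,
                            train = config$train$seed,
                            regime = config$regime$seed))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(config$out_dir)
}
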