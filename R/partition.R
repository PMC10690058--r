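#' Stratified held-out test split
#'
#' Sets aside a stratified test set over *source images*: per class `c`
#' with `n_c` images, `ceiling(test_fraction * n_c)` images are chosen
#' uniformly at random (seeded), so the label ratio of the test set tracks
#' the full dataset. For the 70 + 82 two-class composition at a fraction of
#' 0.2 this holds out 14 + 17 = 31 images.
#'
#' @param dataset an [img_dataset()] of originals (unique source ids).
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with character vectors `test_ids` and `remaining_ids`.
#' @export
stratified_test_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  labs <- source_label_map(dataset)
  classes <- sort(unique(labs))
  if (length(classes) != 2L)
    stopf("expected exactly two classes, got: %s",
          paste(classes, collapse = ", "))
  ids <- sort(names(labs))  # stable order before the seeded shuffle
  test_ids <- with_seed(seed, unlist(lapply(classes, function(cl) {
    pool <- ids[labs[ids] == cl]
    if (length(pool) == 0L) stopf("class '%s' has no images", cl)
    sample(pool, ceiling(test_fraction * length(pool)))
  })))
  list(test_ids = test_ids, remaining_ids = setdiff(ids, test_ids))
}

#' Partition ids into k stratified, non-overlapping folds
#'
#' Ids are shuffled within class (seeded) and dealt round-robin across the
#' folds with a running pointer shared between classes, so fold sizes
#' differ by at most one overall and per-class proportions are as even as
#' the integer constraints allow. 121 ids at `k = 10` give nine folds of 12
#' and one of 13.
#'
#' @param remaining_ids character vector of source ids.
#' @param labels character vector of class labels, parallel to
#'   `remaining_ids` (or named by id).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return A list of `k` character vectors (the validation id sets).
#' @export
make_folds <- function(remaining_ids, labels, k = 10L, seed = 1L) {
  n <- length(remaining_ids)
  if (!is_count(k, 2L)) stopf("k must be an integer >= 2")
  if (k > n) stopf("k = %d exceeds the %d available ids", k, n)
  if (is.null(names(labels))) names(labels) <- remaining_ids
  ord <- sort(remaining_ids)
  folds <- rep(list(character(0L)), k)
  ptr <- 0L
  with_seed(seed, {
    for (cl in sort(unique(labels[ord]))) {
      pool <- sample(ord[labels[ord] == cl])
      for (id in pool) {
        folds[[ptr %% k + 1L]] <- c(folds[[ptr %% k + 1L]], id)
        ptr <- ptr + 1L
      }
    }
  })
  folds
}

#' Full cross-validation split plan
#'
#' Combines the stratified test holdout and the k-fold partition of the
#' remaining source images into one reproducible plan.
#'
#' @param dataset an [img_dataset()] of originals.
#' @param test_fraction test holdout fraction (default 0.2).
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @return An object of class `split_plan` with fields `test_ids`, `folds`,
#'   `k`, `seed`.
#' @export
split_plan <- function(dataset, test_fraction = 0.2, k = 10L, seed = 1L) {
  sp <- stratified_test_split(dataset, test_fraction, seed)
  labs <- source_label_map(dataset)
  folds <- make_folds(sp$remaining_ids, labs[sp$remaining_ids], k, seed)
  structure(list(test_ids = sp$test_ids, folds = folds, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d test ids, %d folds of sizes %s (seed %d)>\n",
              length(x$test_ids), x$k,
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}

#' Serialize / restore a split plan as JSON
#'
#' @param plan a [split_plan()].
#' @param path file path.
#' @return `read_split_plan()` returns the restored `split_plan`.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(test_ids = as.character(unlist(x$test_ids)),
                 folds = lapply(x$folds, function(f) as.character(unlist(f))),
                 k = as.integer(x$k), seed = as.integer(x$seed)),
            class = "split_plan")
}

#' Assemble the augmented training and validation sets for one fold
#'
#' Training images are the augmented variants of all non-test, non-fold
#' source images; validation images are the fold's sources augmented under
#' the same regime. Augmentation happens strictly after splitting, so no
#' augmented variant of a validation (or test) source can ever reach the
#' training set; the test set itself is never augmented.
#'
#' @param dataset the preprocessed [img_dataset()] of originals.
#' @param plan a [split_plan()].
#' @param fold_index which fold is held out for validation (1-based).
#' @param regime an [augmentation_regime()].
#' @return A list with `img_dataset`s `train` and `val`.
#' @export
assemble_fold <- function(dataset, plan, fold_index, regime) {
  stopifnot(inherits(plan, "split_plan"))
  if (!is_count(fold_index, 1L) || fold_index > plan$k)
    stopf("fold_index must be in 1..%d", plan$k)
  val_ids <- plan$folds[[fold_index]]
  train_ids <- setdiff(unlist(plan$folds[-fold_index]), plan$test_ids)
  list(train = compose_regime(dataset_subset(dataset, train_ids), regime),
       val = compose_regime(dataset_subset(dataset, val_ids), regime))
}

#' The untouched, unaugmented test set of a plan
#'
#' @param dataset the preprocessed [img_dataset()] of originals.
#' @param plan a [split_plan()].
#' @return An [img_dataset()] of the test source images, unaugmented.
#' @export
test_set <- function(dataset, plan) {
  dataset_subset(dataset, plan$test_ids)
}
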