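# A bare dataset of n tiny placeholder images per class, cheap to build.
id_dataset <- function(n_by_class) {
  imgs <- unlist(lapply(names(n_by_class), function(cl)
    lapply(seq_len(n_by_class[[cl]]), function(i)
      labelled_image(matrix(0.5, 4L, 4L), cl, sprintf("%s%04d", cl, i)))),
    recursive = FALSE)
  img_dataset(imgs)
}

test_that("the stratified test split takes the per-class ceiling", {
  ds <- id_dataset(c(early = 70L, late = 82L))
  sp <- stratified_test_split(ds, 0.2, seed = 1L)
  labs <- stagernet:::source_label_map(ds)
  expect_length(sp$test_ids, 31L)  # 14 + 17 of 152
  expect_identical(sum(labs[sp$test_ids] == "early"), 14L)
  expect_identical(sum(labs[sp$test_ids] == "late"), 17L)
  expect_length(sp$remaining_ids, 121L)

  sp2 <- stratified_test_split(id_dataset(c(a = 10L, b = 10L)), 0.2)
  expect_length(sp2$test_ids, 4L)

  wing <- stratified_test_split(id_dataset(c(control = 150L,
                                             treated = 119L)), 0.2)
  expect_length(wing$test_ids, 30L + 24L)
  expect_error(stratified_test_split(ds, 0), "test_fraction")
})

test_that("121 remaining ids fold into nine 12s and one 13", {
  ds <- id_dataset(c(early = 70L, late = 82L))
  sp <- stratified_test_split(ds, 0.2, seed = 1L)
  labs <- stagernet:::source_label_map(ds)
  folds <- make_folds(sp$remaining_ids, labs[sp$remaining_ids], k = 10L,
                      seed = 1L)
  expect_identical(sort(lengths(folds)), c(rep(12L, 9L), 13L))
  expect_identical(max(lengths(folds)), 13L)
  expect_setequal(unlist(folds), sp$remaining_ids)
  expect_identical(sum(lengths(folds)), 121L)
  # training size for a 13-fold: 121 - 13 = 108 as printed
  big <- which.max(lengths(folds))
  expect_identical(length(sp$remaining_ids) - lengths(folds)[[big]], 108L)
})

test_that("leave-one-out and error conditions behave", {
  ids <- sprintf("s%02d", 1:8)
  labs <- stats::setNames(rep(c("a", "b"), 4L), ids)
  loo <- make_folds(ids, labs, k = 8L)
  expect_true(all(lengths(loo) == 1L))
  expect_error(make_folds(ids, labs, k = 9L), "exceeds")
  expect_error(make_folds(ids, labs, k = 1L), "k must be")
})

test_that("plans satisfy coverage, disjointness and stratification across seeds", {
  ds <- id_dataset(c(early = 33L, late = 41L))
  labs <- stagernet:::source_label_map(ds)
  all_ids <- sort(dataset_ids(ds))
  for (seed in 1:20) {
    plan <- split_plan(ds, 0.2, k = 5L, seed = seed)
    flat <- unlist(plan$folds)
    # every source is in exactly one of: test set, or one fold
    expect_identical(sort(c(plan$test_ids, flat)), all_ids)
    expect_identical(anyDuplicated(c(plan$test_ids, flat)), 0L)
    expect_lte(diff(range(lengths(plan$folds))), 1L)
    # per-class test proportions within one image of the global ratio
    expect_identical(sum(labs[plan$test_ids] == "early"),
                     as.integer(ceiling(0.2 * 33)))
    expect_identical(sum(labs[plan$test_ids] == "late"),
                     as.integer(ceiling(0.2 * 41)))
    # per-class fold stratification as even as integers allow
    for (cl in c("early", "late")) {
      per <- vapply(plan$folds, function(f) sum(labs[f] == cl), integer(1L))
      expect_lte(diff(range(per)), 1L)
    }
  }
  # same seed reproduces the identical plan; different seeds move members
  p1 <- split_plan(ds, 0.2, k = 5L, seed = 3L)
  p2 <- split_plan(ds, 0.2, k = 5L, seed = 3L)
  expect_identical(p1, p2)
  p3 <- split_plan(ds, 0.2, k = 5L, seed = 4L)
  expect_false(identical(p1$test_ids, p3$test_ids))
})

test_that("plans serialize to JSON and back unchanged", {
  ds <- id_dataset(c(a = 9L, b = 12L))
  plan <- split_plan(ds, 0.25, k = 3L, seed = 6L)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, path)
  expect_identical(read_split_plan(path), plan)
})

test_that("fold assembly augments after splitting and never leaks sources", {
  ds <- tiny_dataset(n_per_class = 5L, side = 32L, seed = 13L)
  plan <- split_plan(ds, 0.2, k = 2L, seed = 13L)
  reg <- augmentation_regime("single", n_angles = 4L, step = 90, seed = 13L)
  for (i in 1:2) {
    fs <- assemble_fold(ds, plan, i, reg)
    tr_ids <- unique(dataset_ids(fs$train))
    va_ids <- unique(dataset_ids(fs$val))
    expect_length(intersect(tr_ids, va_ids), 0L)
    expect_length(intersect(tr_ids, plan$test_ids), 0L)
    expect_length(intersect(va_ids, plan$test_ids), 0L)
    expect_identical(length(fs$train), 4L * length(tr_ids))
    expect_identical(length(fs$val), 4L * length(va_ids))
  }
  # the test set comes back unaugmented
  tst <- test_set(ds, plan)
  expect_true(all(lengths(lapply(tst$images, `[[`, "transform_chain")) == 0L))
  expect_length(tst, 2L)  # ceiling(0.2 * 5) per class
})

test_that("per-fold training expansion reproduces the printed arithmetic", {
  # 121 non-test sources, single regime, 13-source validation fold:
  # 108 x 36 = 3888 training datapoints
  reg <- augmentation_regime("single")
  expect_identical(108L * expansion_factor(reg), 3888L)
})
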