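test_that("rotation enlarges the canvas to the exact bounding box", {
  px <- stagernet:::with_seed(1L, matrix(runif(100), 10L, 10L))
  expect_identical(rotate_enlarge(px, 0), px)
  r45 <- rotate_enlarge(px, 45, resize_back = FALSE)
  expect_identical(dim(r45), rep(as.integer(ceiling(10 * sqrt(2))), 2L))
  r90 <- rotate_enlarge(px, 90, resize_back = FALSE)
  expect_identical(dim(r90), c(10L, 10L))
  # 90 degrees is an exact pixel permutation
  expect_equal(sort(as.vector(r90)), sort(as.vector(px)), tolerance = 1e-9)
  expect_lt(max(abs(rotate_enlarge(r90, -90, resize_back = FALSE) - px)),
            1e-9)
})

test_that("rotation by 180 then horizontal flip equals a vertical flip", {
  px <- matrix(runif(15 * 15), 15L, 15L)
  expect_lt(max(abs(hflip(rotate_enlarge(px, 180, resize_back = FALSE)) -
                      px[rev(seq_len(15L)), ])), 1e-9)
})

test_that("shear, crop and blur reduce to the identity at null parameters", {
  px <- matrix(runif(20 * 20), 20L, 20L)
  expect_lt(max(abs(shear_image(px, 0) - px)), 1e-12)
  expect_identical(crop_image(px, 1), px)
  expect_identical(gaussian_blur(px, 0), px)
  expect_error(crop_image(px, 0), "fraction")
  expect_error(crop_image(px, 1.2), "fraction")
  expect_error(gaussian_blur(px, -1), "sigma")
})

test_that("blur preserves constants and reduces variance on noise", {
  const <- matrix(0.6, 24L, 24L)
  expect_lt(max(abs(gaussian_blur(const, 2) - const)), 1e-9)
  noise <- stagernet:::with_seed(2L, matrix(runif(48 * 48), 48L, 48L))
  inner <- 9:40
  expect_lt(var(as.vector(gaussian_blur(noise, 2)[inner, inner])),
            0.2 * var(as.vector(noise[inner, inner])))
})

test_that("cutout masks exactly the requested boxes and nothing else", {
  px <- matrix(runif(30 * 30), 30L, 30L)
  expect_identical(cutout(px, list(c(5L, 5L, 0L, 0L)), fill = 0), px)
  full <- cutout(px, list(c(1L, 1L, 30L, 30L)), fill = 0.3)
  expect_true(all(full == 0.3))
  one <- cutout(px, list(c(3L, 4L, 5L, 6L)), fill = 0)
  expect_true(all(one[3:7, 4:9] == 0))
  one[3:7, 4:9] <- px[3:7, 4:9]
  expect_identical(one, px)
  # out-of-bounds boxes are clipped, not rejected
  clipped <- cutout(px, list(c(28L, 28L, 10L, 10L)), fill = 0)
  expect_true(all(clipped[28:30, 28:30] == 0))
  expect_identical(clipped[1:27, ], px[1:27, ])
})

test_that("targeted cutout equals box cutout on a box mask and validates dims", {
  px <- matrix(runif(25 * 25), 25L, 25L)
  mask <- matrix(FALSE, 25L, 25L)
  expect_identical(targeted_cutout(px, mask), px)
  expect_true(all(targeted_cutout(px, !mask, fill = 0.1) == 0.1))
  mask[4:9, 7:12] <- TRUE
  expect_identical(targeted_cutout(px, mask, fill = 0),
                   cutout(px, list(c(4L, 7L, 6L, 6L)), fill = 0))
  expect_error(targeted_cutout(px, matrix(TRUE, 5L, 5L)), "dimensions")
})

test_that("hflip is a dimension-preserving involution", {
  px <- matrix(runif(12 * 12), 12L, 12L)
  expect_identical(dim(hflip(px)), dim(px))
  expect_identical(hflip(hflip(px)), px)
  expect_identical(hflip(px)[, 1L], px[, 12L])
})

test_that("baseline rotation yields exactly n_angles variants with inherited identity", {
  ds <- toy_separable_dataset(n_per_class = 1L, side = 16L)
  reg <- augmentation_regime("single")
  out <- apply_baseline(ds, reg)
  expect_length(out, 2L * 36L)
  first <- out$images[seq_len(36L)]
  expect_length(unique(vapply(first, function(im)
    im$transform_chain[[1L]]$angle, numeric(1L))), 36L)
  expect_true(all(vapply(out$images, `[[`, "", "label") ==
                    rep(dataset_labels(ds), each = 36L)))
  expect_true(all(vapply(out$images, `[[`, "", "source_id") ==
                    rep(dataset_ids(ds), each = 36L)))
})

test_that("expansion factors follow the closed form for every mode", {
  ex <- function(...) expansion_factor(augmentation_regime(...))
  blur <- transform_spec("gaussian_blur")
  shr <- transform_spec("shear")
  expect_identical(ex("single"), 36L)
  expect_identical(ex("single", flip = TRUE), 72L)
  expect_identical(ex("additive", extras = list(blur, shr)), 108L)
  expect_identical(ex("choice", extras = list(blur, shr)), 36L)
  expect_identical(ex("combined", extras = list(blur, shr)), 36L)
  expect_identical(ex("sparse", extras = list(transform_spec("mobius"))), 36L)
  # the printed dataset arithmetic: 121 sources
  expect_identical(121L * ex("single"), 4356L)
  expect_identical(121L * ex("additive", extras = list(blur, shr)), 13068L)
  expect_error(augmentation_regime("additive"), "extra")
  expect_error(augmentation_regime("sparse", extras = list(blur, shr)),
               "exactly one")
})

test_that("realized regime sizes equal expansion factor times source count", {
  ds <- tiny_dataset(n_per_class = 2L, side = 32L)
  extras <- list(transform_spec("gaussian_blur", range = c(0.5, 1.5)),
                 transform_spec("crop", range = c(0.85, 0.95)))
  for (mode in c("single", "additive", "choice", "combined")) {
    reg <- augmentation_regime(mode, n_angles = 6L, step = 60,
                               extras = if (mode == "single") list()
                               else extras, seed = 3L)
    out <- compose_regime(ds, reg)
    expect_identical(length(out), length(ds) * expansion_factor(reg))
    expect_setequal(unique(dataset_ids(out)), dataset_ids(ds))
    d <- dim(out$images[[1L]]$pixels)
    rng <- range(vapply(out$images, function(im) range(im$pixels),
                        numeric(2L)))
    expect_identical(d, c(32L, 32L))
    expect_true(rng[1L] >= 0 && rng[2L] <= 1)
  }
})

test_that("sparse augmentation tags exactly round(fraction * N) datapoints", {
  ds <- tiny_dataset(n_per_class = 2L, side = 32L)
  reg <- augmentation_regime("sparse", n_angles = 9L, step = 40,
                             extras = list(transform_spec("mobius")),
                             sparse_fraction = 0.1, seed = 5L)
  out <- compose_regime(ds, reg)
  expect_length(out, 4L * 9L)
  tagged <- vapply(out$images, function(im)
    any(vapply(im$transform_chain, `[[`, "", "name") == "mobius"),
    logical(1L))
  expect_identical(sum(tagged), as.integer(round(0.1 * 36)))
})

test_that("seeded regimes are bit-reproducible and seeds matter", {
  ds <- tiny_dataset(n_per_class = 1L, side = 32L)
  reg <- augmentation_regime("choice", n_angles = 4L, step = 90,
                             extras = list(transform_spec("shear"),
                                           transform_spec("mobius")),
                             seed = 8L)
  a <- compose_regime(ds, reg)
  b <- compose_regime(ds, reg)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
  reg2 <- reg
  reg2$seed <- 9L
  c_ <- compose_regime(ds, reg2)
  expect_false(identical(lapply(a$images, `[[`, "pixels"),
                         lapply(c_$images, `[[`, "pixels")))
})
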