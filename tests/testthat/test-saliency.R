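test_that("smoothgrad with one sample and no noise is the plain gradient map", {
  spec <- build_model(tiny_model_config(side = 16L))
  m <- init_model(spec, seed = 2L)
  img <- stagernet:::with_seed(1L, matrix(runif(256), 16L, 16L))
  sg <- smoothgrad(m, img, n_samples = 1L, noise_sigma = 0,
                   target_class = 1L, normalize = FALSE)
  plain <- abs(stagernet:::net_input_gradient(
    m, array(img, c(16L, 16L, 1L, 1L)), 1L)[, , 1L, 1L])
  expect_equal(sg$attributions, plain, tolerance = 1e-12)
})

test_that("for a linear model the map is the absolute weight grid, whatever the noise", {
  set.seed(14)
  W <- matrix(rnorm(2 * 144), 2L, 144L)
  m <- linear_model(12L, W)
  img <- matrix(runif(144), 12L, 12L)
  want <- matrix(abs(W[2L, ]), 12L, 12L)
  for (sg_args in list(list(n_samples = 1L, noise_sigma = 0),
                       list(n_samples = 10L, noise_sigma = 0.3))) {
    sg <- do.call(smoothgrad, c(list(m, img, target_class = 2L), sg_args))
    expect_equal(sg$attributions, want / max(want), tolerance = 1e-9)
  }
})

test_that("a constant-output model yields an all-zero map", {
  m <- linear_model(10L, matrix(0, 2L, 100L), b = c(3, 1))
  sg <- smoothgrad(m, matrix(runif(100), 10L, 10L), n_samples = 3L,
                   noise_sigma = 0.1, target_class = 1L)
  expect_true(all(sg$attributions == 0))
})

test_that("smoothgrad converges to the plain gradient as the noise vanishes", {
  spec <- build_model(tiny_model_config(side = 16L))
  m <- init_model(spec, seed = 6L)
  img <- stagernet:::with_seed(3L, matrix(runif(256), 16L, 16L))
  plain <- smoothgrad(m, img, 1L, 0, target_class = 1L, normalize = FALSE)
  tiny <- smoothgrad(m, img, 8L, 1e-6, target_class = 1L, normalize = FALSE)
  expect_lt(max(abs(plain$attributions - tiny$attributions)), 1e-4)
})

test_that("low-activation filtering keeps exactly the top quantile", {
  vals <- matrix(sample(1:100) / 100, 10L, 10L)
  expect_identical(filter_low_activation(vals, 0)$attributions, vals)
  f99 <- filter_low_activation(vals, 0.99)
  expect_identical(sum(f99$attributions > 0), 1L)
  expect_identical(f99$attributions[vals == 1], 1)
  # survivors shrink monotonically with the quantile
  nz <- vapply(c(0, 0.25, 0.5, 0.75, 0.9),
               function(q) sum(filter_low_activation(vals, q)$attributions > 0),
               integer(1L))
  expect_true(all(diff(nz) <= 0))
  expect_error(filter_low_activation(vals, 1), "quantile")
})

test_that("mean class maps align by landmark translation and respect bounds", {
  base <- matrix(0, 20L, 20L)
  base[8:12, 8:12] <- matrix(runif(25), 5L, 5L)
  same <- mean_class_map(list(base, base, base),
                         list(c(10, 10), c(10, 10), c(10, 10)))
  expect_equal(same$attributions, base)
  # a shifted copy with a correspondingly shifted landmark realigns exactly
  shifted <- matrix(0, 20L, 20L)
  shifted[13:17, 11:15] <- base[8:12, 8:12]
  mm <- mean_class_map(list(base, shifted), list(c(10, 10), c(15, 13)))
  inner <- 6:15
  expect_equal(mm$attributions[inner, inner], base[inner, inner])
  # bounded by aligned per-pixel extrema
  a <- matrix(runif(400), 20L)
  b <- matrix(runif(400), 20L)
  mab <- mean_class_map(list(a, b), list(c(10, 10), c(10, 10)))
  expect_true(all(mab$attributions >= pmin(a, b) - 1e-12 &
                    mab$attributions <= pmax(a, b) + 1e-12))
  expect_error(mean_class_map(list(a), list(c(30, 10))), "outside")
})

test_that("region scoring counts maps whose surviving mass concentrates in the region", {
  side <- 16L
  hot_in_a <- function() {
    m <- matrix(0, side, side)
    m[3:5, 3:5] <- 1
    m
  }
  hot_out <- function() {
    m <- matrix(0, side, side)
    m[12:14, 12:14] <- 1
    m
  }
  maps <- c(replicate(7L, hot_in_a(), simplify = FALSE),
            replicate(3L, hot_out(), simplify = FALSE))
  masks <- list(A = region_mask_box(side, 2:6, 2:6),
                everywhere = matrix(TRUE, side, side),
                nowhere_near = region_mask_box(side, 8:9, 1:2))
  sc <- score_regions(maps, masks, min_share = 0.1)
  expect_equal(unname(sc["A"]), 0.7)
  expect_equal(unname(sc["everywhere"]), 1.0)
  expect_equal(unname(sc["nowhere_near"]), 0.0)
  expect_error(score_regions(maps, list()), "empty")
  expect_error(score_regions(maps, list(bad = matrix(FALSE, side, side))),
               "TRUE")
})

test_that("region masks round-trip through PNG and polygon JSON", {
  dir <- withr::local_tempdir()
  mask <- region_mask_box(16L, 4:9, 6:11)
  png_path <- file.path(dir, "mask.png")
  EBImage::writeImage(stagernet:::as_ebimage(mask * 1), png_path)
  expect_identical(read_region_mask(png_path), mask)
  js_path <- file.path(dir, "mask.json")
  jsonlite::write_json(list(name = "box", side = 16L,
                            vertices = matrix(c(3.5, 3.5, 9.5, 9.5,
                                                5.5, 11.5, 11.5, 5.5),
                                              4L, 2L)),
                       js_path, auto_unbox = TRUE)
  expect_identical(read_region_mask(js_path), mask)
})

test_that("saliency maps write as CSV and PNG", {
  dir <- withr::local_tempdir()
  spec <- build_model(tiny_model_config(side = 16L))
  m <- init_model(spec, seed = 2L)
  sg <- smoothgrad(m, matrix(runif(256), 16L, 16L), 2L, 0.05,
                   target_class = 1L)
  write_saliency(sg, csv_path = file.path(dir, "s.csv"),
                 png_path = file.path(dir, "s.png"))
  back <- as.matrix(read.csv(file.path(dir, "s.csv"), header = FALSE))
  expect_equal(unname(back), unname(sg$attributions), tolerance = 1e-6)
  expect_true(file.exists(file.path(dir, "s.png")))
})
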