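#' Configuration for the synthetic embryo-image generator
#'
#' Generates two-class greyscale images whose classes differ by two subtle,
#' continuous shape parameters of a smooth blob, emulating the morphological
#' cues used to sub-stage early embryonic brains: the angular width of a
#' "neck" notch cut into the blob outline (analogous to the angle of the
#' prosencephalic neck) and the outline elongation (analogous to
#' prosencephalic width). Nuisance variation in orientation, scale,
#' brightness, contrast and additive noise is layered on top so that the
#' preprocessing, augmentation and training stages all have real work to do.
#'
#' Both class-discriminative parameters are drawn from uniform intervals of
#' fixed width whose centres are pulled apart by `1 - difficulty`: at
#' `difficulty = 0` the class intervals are disjoint (a single threshold on
#' the recorded parameter separates the classes perfectly) and at
#' `difficulty = 1` they coincide, making the classes statistically
#' identical.
#'
#' @param n_per_class images to generate per class (>= 1).
#' @param image_side side of the square image in pixels (>= 32).
#' @param difficulty scalar in `[0, 1]` scaling the overlap of the class
#'   geometry distributions.
#' @param class_names the two class labels.
#' @param nuisance `"moderate"`, `"heavy"`, `"none"`, or a list with fields
#'   `rotation` (degrees, half-range), `scale` (length-2 factor range),
#'   `brightness` (half-range of additive offset), `contrast` (length-2 gain
#'   range) and `noise_sd` (additive Gaussian noise sd).
#' @param neck_center,neck_gap,neck_width centre (degrees), class separation
#'   at difficulty 0, and interval width of the neck-angle distributions.
#' @param elong_center,elong_gap,elong_width same for outline elongation.
#' @param neck_dir direction (degrees) of the neck notch before nuisance
#'   rotation.
#' @param base_radius blob radius as a fraction of the image side.
#' @param confound_orientation if `TRUE`, the neck notch points to
#'   `+confound_angle` degrees for the first class and `-confound_angle` for
#'   the second, adding an orientation confound (mirrored classes) like a
#'   dataset in which treated and control limbs always face opposite ways.
#' @param confound_angle see above.
#' @param seed integer master seed; identical configs produce bit-identical
#'   datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 50L, image_side = 200L,
                             difficulty = 0,
                             class_names = c("early", "late"),
                             nuisance = "moderate",
                             neck_center = 60, neck_gap = 40, neck_width = 20,
                             elong_center = 1.3, elong_gap = 0.3,
                             elong_width = 0.1,
                             neck_dir = 90, base_radius = 0.32,
                             confound_orientation = FALSE,
                             confound_angle = 35,
                             seed = 1L) {
  if (!is_count(n_per_class, 1L)) stopf("n_per_class must be a count >= 1")
  if (!is_count(image_side, 32L)) stopf("image_side must be >= 32")
  if (!is.numeric(difficulty) || difficulty < 0 || difficulty > 1)
    stopf("difficulty must be in [0, 1]")
  stopifnot(length(class_names) == 2L, !anyDuplicated(class_names))
  if (neck_gap <= neck_width)
    stopf("neck_gap must exceed neck_width for disjoint supports at difficulty 0")
  if (elong_gap <= elong_width)
    stopf("elong_gap must exceed elong_width for disjoint supports at difficulty 0")
  if (is.character(nuisance)) {
    nuisance <- switch(match.arg(nuisance, c("moderate", "heavy", "none")),
      moderate = list(rotation = 30, scale = c(0.9, 1.1), brightness = 0.10,
                      contrast = c(0.8, 1.2), noise_sd = 0.05),
      heavy = list(rotation = 90, scale = c(0.75, 1.3), brightness = 0.15,
                   contrast = c(0.7, 1.3), noise_sd = 0.08),
      none = list(rotation = 0, scale = c(1, 1), brightness = 0,
                  contrast = c(1, 1), noise_sd = 0))
  }
  stopifnot(is.list(nuisance),
            all(c("rotation", "scale", "brightness", "contrast", "noise_sd")
                %in% names(nuisance)))
  structure(
    list(n_per_class = as.integer(n_per_class),
         image_side = as.integer(image_side), difficulty = difficulty,
         class_names = class_names, nuisance = nuisance,
         neck_center = neck_center, neck_gap = neck_gap,
         neck_width = neck_width, elong_center = elong_center,
         elong_gap = elong_gap, elong_width = elong_width,
         neck_dir = neck_dir, base_radius = base_radius,
         confound_orientation = confound_orientation,
         confound_angle = confound_angle, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Uniform interval (lo, hi) for a discriminative parameter of class k.
class_interval <- function(center, gap, width, difficulty, k) {
  sign <- if (k == 1L) -1 else 1
  c0 <- center + sign * (1 - difficulty) * gap / 2
  c(c0 - width / 2, c0 + width / 2)
}

#' Generate one synthetic embryo-like image
#'
#' Renders an anti-aliased smooth closed blob (an ellipse of
#' constant area with an angular notch removed) on a noisy constant
#' background, then applies the class geometry and nuisance draws seeded by
#' `draw_seed`. The notch is cut in the parametric angle of the ellipse, so
#' the noise-free blob area has the closed form
#' `pi * a * b * (1 - neck_angle / 360)` and the recorded `neck_angle` is an
#' exactly thresholdable ground-truth parameter.
#'
#' @param class_label one of `config$class_names`.
#' @param config a [synthetic_config()].
#' @param draw_seed integer seed for this image's geometry and nuisance
#'   draws; the same `(class_label, config, draw_seed)` triple always yields
#'   the same pixels.
#' @return A [labelled_image()] whose `geometry` field records the
#'   ground-truth draw (neck angle, elongation, rotation, scale, brightness,
#'   contrast).
#' @export
generate_image <- function(class_label, config, draw_seed) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- match(class_label, config$class_names)
  if (is.na(k))
    stopf("unknown class label '%s'; valid labels: %s", class_label,
          paste(config$class_names, collapse = ", "))
  nu <- config$nuisance
  g <- with_seed(draw_seed, {
    neck_iv <- class_interval(config$neck_center, config$neck_gap,
                              config$neck_width, config$difficulty, k)
    elong_iv <- class_interval(config$elong_center, config$elong_gap,
                               config$elong_width, config$difficulty, k)
    dir0 <- if (isTRUE(config$confound_orientation))
      config$neck_dir + c(1, -1)[k] * config$confound_angle
    else config$neck_dir
    list(neck_angle = runif(1L, neck_iv[1L], neck_iv[2L]),
         elongation = runif(1L, elong_iv[1L], elong_iv[2L]),
         neck_dir = dir0,
         rotation = runif(1L, -nu$rotation, nu$rotation),
         scale = runif(1L, nu$scale[1L], nu$scale[2L]),
         brightness = runif(1L, -nu$brightness, nu$brightness),
         contrast = runif(1L, nu$contrast[1L], nu$contrast[2L]),
         noise_seed = sample.int(.Machine$integer.max - 1L, 1L))
  })
  px <- render_blob(config$image_side, config$base_radius * g$scale,
                    g$elongation, g$neck_angle, g$neck_dir + g$rotation)
  px <- 0.5 + g$contrast * (px - 0.5) + g$brightness
  if (nu$noise_sd > 0)
    px <- px + with_seed(g$noise_seed,
                         matrix(rnorm(length(px), 0, nu$noise_sd),
                                nrow(px), ncol(px)))
  px <- clamp01(px)
  labelled_image(px, class_label,
                 source_id = sprintf("%s_%09d", class_label, draw_seed),
                 geometry = g)
}

# Anti-aliased rendering of the notched ellipse. radius_frac is relative to
# the image side; elongation e stretches the ellipse to semi-axes
# (r * sqrt(e), r / sqrt(e)) keeping the full-ellipse area at pi * r^2.
render_blob <- function(side, radius_frac, elongation, neck_angle, neck_dir,
                        bg = 0.25, fg = 0.85) {
  half <- side / 2
  cx <- (side + 1) / 2
  x <- outer(rep(1, side), (seq_len(side) - cx) / half)  # column coord
  y <- outer((cx - seq_len(side)) / half, rep(1, side))  # row coord, up = +
  r <- 2 * radius_frac
  a <- r * sqrt(elongation)
  b <- r / sqrt(elongation)
  u <- x / a
  v <- y / b
  q <- sqrt(u^2 + v^2)
  edge <- 1.5 / half  # ~1.5 px of smoothing
  cov_ell <- clamp01((1 - q) / edge + 0.5)
  # parametric angle; the notch removes |t - dir| < neck_angle / 2
  t <- atan2(v, u) * 180 / pi
  dd <- (t - neck_dir) %% 360
  dd <- pmin(dd, 360 - dd)
  aedge <- 60 / half  # angular smoothing, shrinks with resolution
  cov_notch <- clamp01((dd - neck_angle / 2) / aedge + 0.5)
  bg + (fg - bg) * cov_ell * cov_notch
}

#' Generate a balanced synthetic dataset
#'
#' @param config a [synthetic_config()].
#' @return An [img_dataset()] with `n_per_class` images per class, unique
#'   source ids and ground-truth geometry stored per image.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_per_class
  draw_seeds <- derive_seeds(config$seed, 2L * n)
  images <- vector("list", 2L * n)
  i <- 0L
  for (k in 1:2)
    for (j in seq_len(n)) {
      i <- i + 1L
      images[[i]] <- generate_image(config$class_names[k], config,
                                    draw_seeds[i])
    }
  img_dataset(images)
}

#' Write a dataset to disk as PNG files plus a manifest
#'
#' @param dataset an [img_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame (columns `path`, `label`,
#'   `source_id`, plus any ground-truth geometry columns).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$images, function(im) {
    fn <- paste0(im$source_id, ".png")
    EBImage::writeImage(as_ebimage(clamp01(im$pixels)), file.path(dir, fn))
    geo <- im$geometry
    cbind(data.frame(path = fn, label = im$label,
                     source_id = im$source_id,
                     stringsAsFactors = FALSE),
          if (!is.null(geo))
            as.data.frame(geo[c("neck_angle", "elongation", "rotation",
                                "scale")]))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
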