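#' Rotate an image, enlarging the canvas so nothing is clipped
#'
#' The canvas grows to the exact bounding box of the rotated frame
#' (`ceil(h|cos| + w|sin|)` by `ceil(w|cos| + h|sin|)`), exposed pixels are
#' filled with the image median, and by default the result is resized back
#' to the input side. Because rotated content is scaled down to fit, a
#' rotation-augmented dataset also carries scale variation, which is
#' intentional.
#'
#' @param pixels numeric matrix.
#' @param angle_degrees rotation angle, counterclockwise.
#' @param fill fill value for exposed canvas (default image median).
#' @param resize_back resize the enlarged canvas back to the input size
#'   (default `TRUE`).
#' @return A numeric matrix; same dimensions as the input when
#'   `resize_back = TRUE`.
#' @export
rotate_enlarge <- function(pixels, angle_degrees,
                           fill = stats::median(pixels),
                           resize_back = TRUE) {
  stopifnot(is.matrix(pixels), is.finite(angle_degrees))
  H <- nrow(pixels)
  W <- ncol(pixels)
  th <- angle_degrees * pi / 180
  co <- cos(th)
  si <- sin(th)
  H2 <- as.integer(ceiling(H * abs(co) + W * abs(si) - 1e-9))
  W2 <- as.integer(ceiling(W * abs(co) + H * abs(si) - 1e-9))
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  cy2 <- (H2 + 1) / 2
  cx2 <- (W2 + 1) / 2
  dxu <- outer(rep(1, H2), seq_len(W2) - cx2)
  dyu <- outer(cy2 - seq_len(H2), rep(1, W2))
  sr <- cy - (-si * dxu + co * dyu)
  sc <- cx + (co * dxu + si * dyu)
  out <- warp_bilinear(pixels, sr, sc, fill)
  if (resize_back && !(H2 == H && W2 == W)) out <- resize_image(out, H)
  out
}

#' Affine shear
#'
#' Horizontal shear by `shear_degrees` about the image centre; the canvas
#' is unchanged and exposed pixels take the fill value.
#'
#' @param pixels numeric matrix.
#' @param shear_degrees shear angle in degrees.
#' @param fill fill value (default image median).
#' @return A matrix of the same dimensions.
#' @export
shear_image <- function(pixels, shear_degrees,
                        fill = stats::median(pixels)) {
  stopifnot(is.matrix(pixels), is.finite(shear_degrees))
  H <- nrow(pixels)
  W <- ncol(pixels)
  cy <- (H + 1) / 2
  cx <- (W + 1) / 2
  tn <- tan(shear_degrees * pi / 180)
  dyu <- outer(cy - seq_len(H), rep(1, W))
  sc <- outer(rep(1, H), seq_len(W)) - tn * dyu
  sr <- outer(seq_len(H), rep(1, W))
  warp_bilinear(pixels, sr, sc, fill)
}

#' Crop a centred window and resize back
#'
#' Retains a centred window containing `fraction` of the image area, then
#' resizes it back to the input side.
#'
#' @param pixels numeric matrix (square).
#' @param fraction area fraction retained, in `(0, 1]`.
#' @return A matrix of the same dimensions.
#' @export
crop_image <- function(pixels, fraction) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stopf("crop fraction must be in (0, 1]")
  if (fraction == 1) return(pixels)
  S <- nrow(pixels)
  w <- max(1L, round(S * sqrt(fraction)))
  off <- floor((S - w) / 2)
  win <- pixels[(off + 1L):(off + w), (off + 1L):(off + w), drop = FALSE]
  resize_image(win, S)
}

#' Gaussian blur
#'
#' Isotropic Gaussian convolution (via EBImage); `sigma = 0` is the
#' identity.
#'
#' @param pixels numeric matrix.
#' @param sigma kernel standard deviation in pixels (>= 0).
#' @return A matrix of the same dimensions.
#' @export
gaussian_blur <- function(pixels, sigma) {
  if (!is.numeric(sigma) || sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(pixels)
  # kernel radius capped (odd, within the image) so small images stay legal
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                min(dim(pixels)) - 1L + min(dim(pixels)) %% 2L)
  from_ebimage(EBImage::gblur(as_ebimage(pixels), sigma = sigma,
                              radius = radius))
}

#' Cutout: mask rectangular boxes with a fill value
#'
#' Pixels inside the boxes are replaced by `fill`; everything else is
#' untouched. Boxes extending beyond the image are clipped, not rejected.
#'
#' @param pixels numeric matrix.
#' @param boxes list of boxes, each `c(row, col, height, width)` giving the
#'   top-left corner and size; zero-area boxes are allowed.
#' @param fill fill value (default image median).
#' @return A matrix of the same dimensions.
#' @export
cutout <- function(pixels, boxes, fill = stats::median(pixels)) {
  stopifnot(is.list(boxes))
  for (b in boxes) {
    stopifnot(length(b) == 4L)
    r0 <- max(1L, as.integer(b[1L]))
    c0 <- max(1L, as.integer(b[2L]))
    r1 <- min(nrow(pixels), as.integer(b[1L]) + as.integer(b[3L]) - 1L)
    c1 <- min(ncol(pixels), as.integer(b[2L]) + as.integer(b[4L]) - 1L)
    if (r1 >= r0 && c1 >= c0) pixels[r0:r1, c0:c1] <- fill
  }
  pixels
}

#' Targeted cutout: mask an arbitrary named region
#'
#' Replaces the pixels under a boolean mask with the fill value; used to
#' ablate a named feature (such as a gene-expression domain) across a whole
#' dataset before training, to test whether the classifier relies on it.
#'
#' @param pixels numeric matrix.
#' @param region_mask logical matrix of the same dimensions.
#' @param fill fill value (default image median).
#' @return A matrix of the same dimensions.
#' @export
targeted_cutout <- function(pixels, region_mask,
                            fill = stats::median(pixels)) {
  if (!identical(dim(pixels), dim(region_mask)))
    stopf("region_mask dimensions (%s) do not match image (%s)",
          paste(dim(region_mask), collapse = "x"),
          paste(dim(pixels), collapse = "x"))
  pixels[region_mask] <- fill
  pixels
}

#' Horizontal flip
#'
#' Mirror about the vertical midline. An involution:
#' `hflip(hflip(x)) == x`.
#'
#' @param pixels numeric matrix.
#' @return The mirrored matrix.
#' @export
hflip <- function(pixels) pixels[, rev(seq_len(ncol(pixels))), drop = FALSE]

#' Declare an augmentation regime
#'
#' A declarative recipe that deterministically expands a dataset. The
#' baseline is the full set of `n_angles` rotations at `step` degrees
#' (including 0 degrees, so each original is a member of its own variant
#' set), optionally preceded by horizontal flips for data whose classes are
#' orientation-confounded. Modes:
#'
#' * `single`: baseline rotations only; expansion = `n_angles * (1+flip)`.
#' * `additive`: the baseline plus, for each extra transform, a transformed
#'   copy of every rotated variant; expansion multiplied by
#'   `1 + length(extras)`.
#' * `choice`: every rotated variant additionally receives one extra
#'   transform drawn uniformly at random (no size change).
#' * `combined`: every extra transform is applied in sequence on top of
#'   each rotated variant (no size change).
#' * `sparse`: exactly `round(sparse_fraction * N)` of the baseline
#'   datapoints, chosen uniformly without replacement, additionally receive
#'   the single extra transform (no size change).
#'
#' @param mode one of `"single"`, `"additive"`, `"choice"`, `"combined"`,
#'   `"sparse"`.
#' @param n_angles number of rotations (default 36).
#' @param step rotation step in degrees (default 10).
#' @param flip include horizontally flipped copies in the baseline.
#' @param extras list of transform specs, each created by
#'   [transform_spec()].
#' @param sparse_fraction proportion of datapoints receiving the sparse
#'   transform (default 0.1).
#' @param seed integer seed making random parameter draws reproducible.
#' @return An object of class `augmentation_regime`.
#' @export
augmentation_regime <- function(mode = "single", n_angles = 36L, step = 10,
                                flip = FALSE, extras = list(),
                                sparse_fraction = 0.1, seed = 1L) {
  mode <- match.arg(mode, c("single", "additive", "choice", "combined",
                            "sparse"))
  if (!is_count(n_angles, 1L)) stopf("n_angles must be a count >= 1")
  if (mode %in% c("additive", "choice", "combined") && length(extras) == 0L)
    stopf("mode '%s' requires at least one extra transform", mode)
  if (mode == "sparse") {
    if (length(extras) != 1L)
      stopf("sparse mode requires exactly one extra transform")
    if (sparse_fraction <= 0 || sparse_fraction > 1)
      stopf("sparse_fraction must be in (0, 1]")
  }
  structure(list(mode = mode, n_angles = as.integer(n_angles), step = step,
                 flip = isTRUE(flip), extras = extras,
                 sparse_fraction = sparse_fraction, seed = as.integer(seed)),
            class = "augmentation_regime")
}

#' @export
print.augmentation_regime <- function(x, ...) {
  cat(sprintf(
    "<augmentation_regime mode=%s, %d rotations x %g deg%s, extras: %s (expansion x%d)>\n",
    x$mode, x$n_angles, x$step, if (x$flip) " + hflip" else "",
    if (length(x$extras)) paste(vapply(x$extras, `[[`, "", "name"),
                                collapse = ", ") else "none",
    expansion_factor(x)))
  invisible(x)
}

#' Transform specification for a regime
#'
#' @param name one of `"crop"`, `"shear"`, `"gaussian_blur"`, `"cutout"`,
#'   `"targeted_cutout"`, `"mobius"`, `"hflip"`.
#' @param ... parameter ranges overriding the defaults: `range` for
#'   crop/shear/blur (length-2 numeric), `n_boxes`/`box_frac` for cutout,
#'   `jitter` for mobius, `mask` for targeted_cutout.
#' @return A named list usable in [augmentation_regime()]'s `extras`.
#' @export
transform_spec <- function(name, ...) {
  name <- match.arg(name, c("crop", "shear", "gaussian_blur", "cutout",
                            "targeted_cutout", "mobius", "hflip"))
  defaults <- switch(name,
    crop = list(range = c(0.8, 1.0)),
    shear = list(range = c(-20, 20)),
    gaussian_blur = list(range = c(0, 3)),
    cutout = list(n_boxes = c(1L, 3L), box_frac = c(0.10, 0.25)),
    targeted_cutout = list(mask = NULL),
    mobius = list(jitter = 0.15),
    hflip = list())
  spec <- utils::modifyList(defaults, list(...))
  c(list(name = name), spec)
}

#' Closed-form expansion factor of a regime
#'
#' The realized dataset size is always `expansion_factor(regime)` times the
#' number of source images, for every mode; this is computable before any
#' pixels are touched.
#'
#' @param regime an [augmentation_regime()].
#' @return Integer expansion factor.
#' @export
expansion_factor <- function(regime) {
  stopifnot(inherits(regime, "augmentation_regime"))
  base <- regime$n_angles * (1L + as.integer(regime$flip))
  if (regime$mode == "additive") base * (1L + length(regime$extras)) else base
}

# Apply one extra transform with parameters drawn from the current RNG
# stream; appends a descriptor to the image's transform chain.
apply_extra <- function(im, spec) {
  px <- im$pixels
  desc <- switch(spec$name,
    crop = {
      f <- runif(1L, spec$range[1L], spec$range[2L])
      px <- crop_image(px, f)
      list(name = "crop", fraction = f)
    },
    shear = {
      s <- runif(1L, spec$range[1L], spec$range[2L])
      px <- shear_image(px, s)
      list(name = "shear", degrees = s)
    },
    gaussian_blur = {
      s <- runif(1L, spec$range[1L], spec$range[2L])
      px <- gaussian_blur(px, s)
      list(name = "gaussian_blur", sigma = s)
    },
    cutout = {
      nb <- sample(spec$n_boxes[1L]:spec$n_boxes[2L], 1L)
      S <- nrow(px)
      boxes <- lapply(seq_len(nb), function(i) {
        side <- round(runif(1L, spec$box_frac[1L], spec$box_frac[2L]) * S)
        c(sample.int(S - side + 1L, 1L), sample.int(S - side + 1L, 1L),
          side, side)
      })
      px <- cutout(px, boxes)
      list(name = "cutout", boxes = boxes)
    },
    targeted_cutout = {
      px <- targeted_cutout(px, spec$mask)
      list(name = "targeted_cutout")
    },
    mobius = {
      p <- sample_mobius_params(spec$jitter)
      px <- mobius_warp(px, p)
      list(name = "mobius", params = unclass(p))
    },
    hflip = {
      px <- hflip(px)
      list(name = "hflip")
    },
    stopf("unknown transform '%s'", spec$name))
  im$pixels <- clamp01(px)
  im$transform_chain <- c(im$transform_chain, list(desc))
  im
}

#' Expand a dataset with the baseline rotations
#'
#' Each input image (and, if the regime says so, its horizontal flip)
#' yields exactly `n_angles` rotated variants at angles `k * step`,
#' `k = 0 .. n_angles - 1`, with labels and source ids inherited.
#'
#' @param dataset an [img_dataset()] of originals.
#' @param regime an [augmentation_regime()] (only its baseline fields are
#'   used).
#' @return The rotation-expanded [img_dataset()].
#' @export
apply_baseline <- function(dataset, regime) {
  stopifnot(inherits(regime, "augmentation_regime"))
  angles <- (seq_len(regime$n_angles) - 1L) * regime$step
  out <- vector("list", length(dataset) * expansion_factor(
    augmentation_regime("single", regime$n_angles, regime$step,
                        regime$flip)))
  i <- 0L
  for (im in dataset$images) {
    variants <- list(im)
    if (regime$flip) {
      fl <- im
      fl$pixels <- hflip(im$pixels)
      fl$transform_chain <- c(im$transform_chain, list(list(name = "hflip")))
      variants <- c(variants, list(fl))
    }
    for (v in variants)
      for (ang in angles) {
        i <- i + 1L
        rv <- v
        if (ang != 0) rv$pixels <- clamp01(rotate_enlarge(v$pixels, ang))
        rv$transform_chain <- c(v$transform_chain,
                                list(list(name = "rotate", angle = ang)))
        out[[i]] <- rv
      }
  }
  img_dataset(out)
}

#' Expand a dataset under a full augmentation regime
#'
#' Applies the baseline rotations (and flips) and then the mode-specific
#' extra transforms; see [augmentation_regime()] for the semantics of each
#' mode. The realized size always equals
#' `expansion_factor(regime) * length(dataset)`, labels and source ids are
#' inherited unchanged, and identical seeds give bit-identical output.
#'
#' @param dataset an [img_dataset()] of originals.
#' @param regime an [augmentation_regime()].
#' @return The expanded [img_dataset()].
#' @export
compose_regime <- function(dataset, regime) {
  stopifnot(inherits(dataset, "img_dataset"),
            inherits(regime, "augmentation_regime"))
  with_seed(regime$seed, {
    rotated <- apply_baseline(dataset, regime)
    switch(regime$mode,
      single = rotated,
      additive = {
        blocks <- lapply(regime$extras, function(spec)
          lapply(rotated$images, apply_extra, spec = spec))
        img_dataset(c(rotated$images, unlist(blocks, recursive = FALSE)))
      },
      choice = {
        picks <- sample.int(length(regime$extras), length(rotated),
                            replace = TRUE)
        img_dataset(Map(function(im, k) apply_extra(im, regime$extras[[k]]),
                        rotated$images, picks))
      },
      combined = {
        img_dataset(lapply(rotated$images, function(im) {
          for (spec in regime$extras) im <- apply_extra(im, spec)
          im
        }))
      },
      sparse = {
        n_aug <- round(regime$sparse_fraction * length(rotated))
        idx <- sample.int(length(rotated), n_aug)
        for (i in idx)
          rotated$images[[i]] <- apply_extra(rotated$images[[i]],
                                             regime$extras[[1L]])
        rotated
      })
  })
}
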