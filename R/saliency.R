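#' SmoothGrad saliency map
#'
#' Averages the input-gradient of the target-class pre-softmax score over
#' `n_samples` noise-perturbed copies of the image (Gaussian noise with
#' standard deviation `noise_sigma` on the intensity scale), then reduces
#' to a nonnegative attribution grid by taking the absolute value and
#' max-normalizing to `[0, 1]`. With `n_samples = 1` and `noise_sigma = 0`
#' this is the plain input-gradient map.
#'
#' @param model a trained `stagernet_model`.
#' @param image square numeric matrix matching the model input side.
#' @param n_samples number of noise samples (default 20).
#' @param noise_sigma noise sd as a fraction of the intensity range
#'   (default 0.1).
#' @param target_class class index (or name, if the model holds class
#'   names) whose score is attributed; defaults to the predicted class.
#' @param seed integer seed for the noise draws.
#' @param normalize max-normalize the attribution grid (default `TRUE`).
#' @return An object of class `saliency_map`: a list with the nonnegative
#'   `attributions` matrix and the call metadata.
#' @export
smoothgrad <- function(model, image, n_samples = 20L, noise_sigma = 0.1,
                       target_class = NULL, seed = 1L, normalize = TRUE) {
  stopifnot(inherits(model, "stagernet_model"), is.matrix(image),
            is_count(n_samples, 1L), noise_sigma >= 0)
  nc <- model$spec$config$n_classes
  X <- array(image, c(dim(image), 1L, 1L))
  if (is.character(target_class)) {
    target_class <- match(target_class, model$class_names)
    if (is.na(target_class)) stopf("unknown target class")
  }
  if (is.null(target_class)) {
    target_class <- which.max(net_predict_probs(model, X)[, 1L])
  } else if (!is_count(target_class, 1L) || target_class > nc) {
    stopf("target_class must be a class index in 1..%d", nc)
  }
  g <- with_seed(seed, {
    acc <- matrix(0, nrow(image), ncol(image))
    for (s in seq_len(n_samples)) {
      Xs <- if (noise_sigma > 0)
        X + array(rnorm(length(X), 0, noise_sigma), dim(X)) else X
      acc <- acc + net_input_gradient(model, Xs, target_class)[, , 1L, 1L]
    }
    acc / n_samples
  })
  att <- abs(g)
  if (normalize && max(att) > 0) att <- att / max(att)
  structure(list(attributions = att, n_samples = as.integer(n_samples),
                 noise_sigma = noise_sigma, target_class = target_class,
                 source_id = NULL),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "<saliency_map %dx%d: n_samples=%d, sigma=%g, target class %d, %d nonzero px>\n",
    nrow(x$attributions), ncol(x$attributions), x$n_samples, x$noise_sigma,
    x$target_class, sum(x$attributions > 0)))
  invisible(x)
}

as_saliency <- function(att, template = NULL) {
  structure(list(attributions = att,
                 n_samples = template$n_samples %||% NA_integer_,
                 noise_sigma = template$noise_sigma %||% NA_real_,
                 target_class = template$target_class %||% NA_integer_,
                 source_id = template$source_id),
            class = "saliency_map")
}

sal_att <- function(m) if (inherits(m, "saliency_map")) m$attributions else m

#' Filter out low-level activations
#'
#' Sets attributions strictly below the per-map `quantile` to zero,
#' leaving the rest unchanged, so only the strongest attention survives.
#'
#' @param map a `saliency_map` (or plain matrix).
#' @param quantile quantile in `[0, 1)` below which attributions are
#'   zeroed (default 0.75).
#' @return A `saliency_map`.
#' @export
filter_low_activation <- function(map, quantile = 0.75) {
  if (quantile < 0 || quantile >= 1) stopf("quantile must be in [0, 1)")
  att <- sal_att(map)
  thr <- stats::quantile(att, quantile, names = FALSE)
  att[att < thr] <- 0
  as_saliency(att, if (inherits(map, "saliency_map")) map)
}

#' Landmark-aligned mean saliency map of a class
#'
#' Translates each map so its reference landmark (for embryo images, the
#' anterior neuropore) coincides with `target_point`, then averages
#' pixel-wise; positions a given map does not cover after translation are
#' excluded from that pixel's average rather than contributing zeros.
#'
#' @param maps list of `saliency_map`s (or matrices) of equal dimensions.
#' @param reference_points list (or 2-column matrix) of `(row, col)`
#'   landmark positions, one per map.
#' @param target_point `(row, col)` the landmarks are moved to; defaults
#'   to the image centre.
#' @return A `saliency_map` holding the aligned mean.
#' @export
mean_class_map <- function(maps, reference_points, target_point = NULL) {
  stopifnot(length(maps) >= 1L)
  atts <- lapply(maps, sal_att)
  d <- dim(atts[[1L]])
  if (!all(vapply(atts, function(a) identical(dim(a), d), logical(1L))))
    stopf("all maps must have identical dimensions")
  if (is.matrix(reference_points))
    reference_points <- asplit(reference_points, 1L)
  stopifnot(length(reference_points) == length(maps))
  tp <- target_point %||% c((d[1L] + 1) %/% 2, (d[2L] + 1) %/% 2)
  acc <- matrix(0, d[1L], d[2L])
  cnt <- matrix(0L, d[1L], d[2L])
  for (i in seq_along(atts)) {
    rp <- round(as.numeric(reference_points[[i]]))
    if (rp[1L] < 1 || rp[1L] > d[1L] || rp[2L] < 1 || rp[2L] > d[2L])
      stopf("reference point (%g, %g) of map %d lies outside the image",
            rp[1L], rp[2L], i)
    dr <- tp[1L] - rp[1L]
    dc <- tp[2L] - rp[2L]
    src_r <- (max(1, 1 + dr)):(min(d[1L], d[1L] + dr)) - dr
    src_c <- (max(1, 1 + dc)):(min(d[2L], d[2L] + dc)) - dc
    acc[src_r + dr, src_c + dc] <- acc[src_r + dr, src_c + dc] +
      atts[[i]][src_r, src_c]
    cnt[src_r + dr, src_c + dc] <- cnt[src_r + dr, src_c + dc] + 1L
  }
  out <- acc / pmax(cnt, 1L)
  as_saliency(out, if (inherits(maps[[1L]], "saliency_map")) maps[[1L]])
}

#' Score named regions against a set of saliency maps
#'
#' For each region mask, the fraction of maps that "focus" there: by
#' default a map focuses on a region when the region contains at least
#' `min_share` of the map's total surviving attribution mass (apply
#' [filter_low_activation()] first to restrict to high-level attention).
#'
#' @param maps list of (typically filtered) `saliency_map`s or matrices.
#' @param region_masks named list of logical matrices at map resolution,
#'   each with at least one `TRUE` pixel.
#' @param min_share share of surviving attribution mass required to count
#'   as focus (default 0.1).
#' @return Named numeric vector of per-region fractions in `[0, 1]`.
#' @export
score_regions <- function(maps, region_masks, min_share = 0.1) {
  if (length(region_masks) == 0L) stopf("empty region mask set")
  stopifnot(length(maps) >= 1L)
  atts <- lapply(maps, sal_att)
  d <- dim(atts[[1L]])
  for (nm in names(region_masks)) {
    m <- region_masks[[nm]]
    if (!identical(dim(m), d)) stopf("mask '%s' dimensions mismatch", nm)
    if (!any(m)) stopf("mask '%s' has no TRUE pixel", nm)
  }
  vapply(region_masks, function(mask) {
    mean(vapply(atts, function(a) {
      tot <- sum(a)
      tot > 0 && sum(a[mask]) >= min_share * tot
    }, logical(1L)))
  }, numeric(1L))
}

#' Construct, read and write region masks
#'
#' `region_mask_box()` builds a rectangular mask; `read_region_mask()`
#' reads one from a label PNG (pixels > 0.5 are in the region) or from a
#' polygon JSON file with fields `name` and `vertices` (a list of
#' `[row, col]` pairs, even-odd filled).
#'
#' @param side image side in pixels.
#' @param rows,cols integer ranges of the box.
#' @return A logical matrix.
#' @export
region_mask_box <- function(side, rows, cols) {
  m <- matrix(FALSE, side, side)
  m[rows, cols] <- TRUE
  m
}

#' @rdname region_mask_box
#' @param path PNG or JSON file path.
#' @export
read_region_mask <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    v <- js$vertices
    stopifnot(!is.null(js$side), is.matrix(v), ncol(v) == 2L)
    pts <- expand.grid(row = seq_len(js$side), col = seq_len(js$side))
    inside <- point_in_polygon(pts$row, pts$col, v[, 1L], v[, 2L])
    matrix(inside, js$side, js$side)
  } else {
    from_ebimage(EBImage::readImage(path)) > 0.5
  }
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Write a saliency map to disk
#'
#' Writes the raw attribution matrix as CSV and, optionally, a greyscale
#' PNG heat image.
#'
#' @param map a `saliency_map`.
#' @param csv_path CSV output path (`NULL` to skip).
#' @param png_path PNG output path (`NULL` to skip).
#' @return Invisibly, the map.
#' @export
write_saliency <- function(map, csv_path = NULL, png_path = NULL) {
  att <- sal_att(map)
  if (!is.null(csv_path))
    write.table(att, csv_path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  if (!is.null(png_path)) {
    mx <- max(att)
    EBImage::writeImage(as_ebimage(if (mx > 0) att / mx else att), png_path)
  }
  invisible(map)
}
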