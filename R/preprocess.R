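#' Convert an image to greyscale
#'
#' Single-channel inputs are returned unchanged; 3-channel inputs are
#' combined with the Rec.601 luminance weights (0.299, 0.587, 0.114).
#'
#' @param pixels a numeric matrix (already greyscale), an `(H, W, 1)` array,
#'   or an `(H, W, 3)` array.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  d <- dim(pixels)
  if (length(d) == 3L && d[3L] == 1L) return(pixels[, , 1L])
  if (length(d) == 3L && d[3L] == 3L)
    return(0.299 * pixels[, , 1L] + 0.587 * pixels[, , 2L] +
             0.114 * pixels[, , 3L])
  stopf("unsupported channel count: expected 1 or 3 channels")
}

#' Resize an image to a square
#'
#' Bilinear interpolation (via EBImage); non-square inputs are stretched,
#' not padded, so the aspect ratio is not preserved.
#'
#' @param pixels numeric matrix.
#' @param side target side in pixels (>= 8).
#' @return A `side` x `side` numeric matrix.
#' @export
resize_image <- function(pixels, side = 200L) {
  if (!is_count(side, 8L)) stopf("side must be a positive integer >= 8")
  stopifnot(is.matrix(pixels))
  if (nrow(pixels) == side && ncol(pixels) == side) return(pixels)
  shrinking <- side < max(nrow(pixels), ncol(pixels))
  from_ebimage(EBImage::resize(as_ebimage(pixels), w = side, h = side,
                               filter = "bilinear",
                               antialias = shrinking))
}

#' Global histogram equalization
#'
#' Remaps intensities through the empirical cumulative distribution on 256
#' bins, brightening globally dark images and darkening bright ones. The
#' map is monotone non-decreasing, so the rank order of pixel intensities
#' is never reversed; constant images are returned unchanged; an image
#' whose histogram is already uniform over the bins is reproduced to within
#' one quantization level.
#'
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param levels number of histogram bins (default 256).
#' @return A numeric matrix in `[0, 1]`.
#' @export
normalize_histogram <- function(pixels, levels = 256L) {
  stopifnot(is.matrix(pixels))
  v <- clamp01(pixels)
  if (max(v) == min(v)) return(pixels)
  bins <- as.integer(floor(v * (levels - 1L) + 0.5))  # 0 .. levels-1
  h <- tabulate(bins + 1L, nbins = levels)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0L])
  n <- length(v)
  map <- (cdf - cdf_min) / max(n - cdf_min, 1L)
  matrix(map[bins + 1L], nrow(pixels), ncol(pixels))
}

#' Standard preprocessing pipeline
#'
#' Greyscale conversion, then resize to a fixed square, then global
#' histogram equalization, in that order (the order of the last two steps
#' can be swapped with `equalize_first = TRUE`).
#'
#' @param pixels image matrix or 3-channel array.
#' @param side target side (default 200).
#' @param equalize_first equalize before resizing instead of after.
#' @return A `side` x `side` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(pixels, side = 200L, equalize_first = FALSE) {
  px <- to_grayscale(pixels)
  if (equalize_first) {
    px <- normalize_histogram(px)
    px <- resize_image(px, side)
  } else {
    px <- resize_image(px, side)
    px <- normalize_histogram(px)
  }
  clamp01(px)
}

#' Preprocess every image in a dataset
#'
#' @param dataset an [img_dataset()].
#' @inheritParams preprocess_image
#' @return The dataset with every image preprocessed (labels, source ids
#'   and provenance untouched).
#' @export
preprocess_dataset <- function(dataset, side = 200L, equalize_first = FALSE) {
  dataset$images <- lapply(dataset$images, function(im) {
    im$pixels <- preprocess_image(im$pixels, side, equalize_first)
    im
  })
  dataset
}
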