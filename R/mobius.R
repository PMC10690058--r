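#' Moebius transformations of the complex plane
#'
#' A Moebius transformation is the bijective conformal map
#' `w = (a z + b) / (c z + d)` with `a d - b c != 0`. Applied as an image
#' warp it produces smooth, angle-preserving distortions of the kind seen
#' when specimens bend or are damaged during preparation, which makes it a
#' biologically plausible augmentation for microscopy images.
#'
#' @param a,b,c,d complex (or numeric) coefficients; `a d - b c` must be
#'   nonzero.
#' @return An object of class `mobius_params`.
#' @export
mobius_params <- function(a, b, c, d) {
  p <- complex(real = Re(c(a, b, c, d)), imaginary = Im(c(a, b, c, d)))
  if (any(!is.finite(p))) stopf("Moebius coefficients must be finite")
  if (abs(p[1L] * p[4L] - p[2L] * p[3L]) == 0)
    stopf("degenerate Moebius parameters: a*d - b*c = 0")
  structure(list(a = p[1L], b = p[2L], c = p[3L], d = p[4L]),
            class = "mobius_params")
}

#' @export
print.mobius_params <- function(x, ...) {
  cat(sprintf("<mobius_params w = (%s z + %s) / (%s z + %s)>\n",
              format(x$a), format(x$b), format(x$c), format(x$d)))
  invisible(x)
}

#' Apply a Moebius map to points
#'
#' Vectorized over `z`. The pole `z = -d/c` maps to the point at infinity,
#' returned as a complex infinity rather than raising an error or
#' overflowing.
#'
#' @param z complex vector.
#' @param params a [mobius_params()].
#' @return Complex vector `(a z + b) / (c z + d)`.
#' @export
mobius_point <- function(z, params) {
  stopifnot(inherits(params, "mobius_params"))
  den <- params$c * z + params$d
  w <- (params$a * z + params$b) / den
  w[abs(den) == 0] <- complex(real = Inf, imaginary = Inf)
  w
}

#' Compose and invert Moebius maps
#'
#' Coefficients compose as 2x2 matrix products:
#' `mobius_compose(p2, p1)` is the map `z -> p2(p1(z))`.
#'
#' @param p1,p2,params [mobius_params()] objects.
#' @return A [mobius_params()].
#' @export
mobius_compose <- function(p2, p1) {
  mobius_params(p2$a * p1$a + p2$b * p1$c, p2$a * p1$b + p2$b * p1$d,
                p2$c * p1$a + p2$d * p1$c, p2$c * p1$b + p2$d * p1$d)
}

#' @rdname mobius_compose
#' @export
mobius_inverse <- function(params) {
  mobius_params(params$d, -params$b, -params$c, params$a)
}

#' Moebius map sending three points to three points
#'
#' Solves for the unique Moebius transformation with `w_i = f(z_i)`,
#' `i = 1..3`, via the standard construction through `(0, 1, Inf)`.
#'
#' @param z,w length-3 complex vectors of distinct source and target points.
#' @return A [mobius_params()].
#' @export
mobius_from_points <- function(z, w) {
  stopifnot(length(z) == 3L, length(w) == 3L)
  to01inf <- function(p) {
    # matrix of the map sending p1, p2, p3 to 0, 1, Inf
    matrix(c(p[2L] - p[3L], p[2L] - p[1L],
             -p[1L] * (p[2L] - p[3L]), -p[3L] * (p[2L] - p[1L])), 2L, 2L)
  }
  A <- to01inf(z)
  B <- to01inf(w)
  Binv <- matrix(c(B[2L, 2L], -B[2L, 1L], -B[1L, 2L], B[1L, 1L]), 2L, 2L)
  M <- Binv %*% A
  mobius_params(M[1L, 1L], M[1L, 2L], M[2L, 1L], M[2L, 2L])
}

#' Cross-ratio of four points
#'
#' The cross-ratio `((z1-z3)(z2-z4)) / ((z1-z4)(z2-z3))` is invariant under
#' every Moebius transformation.
#'
#' @param z1,z2,z3,z4 complex scalars or vectors.
#' @return Complex cross-ratio.
#' @export
cross_ratio <- function(z1, z2, z3, z4) {
  ((z1 - z3) * (z2 - z4)) / ((z1 - z4) * (z2 - z3))
}

# Complex-plane embedding of the pixel grid: pixel (row, col) maps to
# z = (col - cx)/half + i (cx - row)/half, so the image occupies roughly the
# unit disc regardless of resolution and parameters are centre-anchored.
pixel_to_z <- function(side) {
  half <- side / 2
  cx <- (side + 1) / 2
  cols <- outer(rep(1, side), seq_len(side))
  rows <- outer(seq_len(side), rep(1, side))
  complex(real = (cols - cx) / half, imaginary = (cx - rows) / half)
}

#' Warp an image with a Moebius transformation
#'
#' Inverse-mapped warp: each output pixel samples the input at the inverse
#' Moebius image of its complex-plane coordinate, with bilinear
#' interpolation; samples falling outside the input (or at the pole) take
#' the fill value.
#'
#' @param pixels square numeric matrix.
#' @param params a [mobius_params()].
#' @param fill fill intensity for out-of-domain samples; defaults to the
#'   image median so no artificial border cue is introduced.
#' @return A warped matrix of the same dimensions.
#' @export
mobius_warp <- function(pixels, params, fill = stats::median(pixels)) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  side <- nrow(pixels)
  half <- side / 2
  cx <- (side + 1) / 2
  zsrc <- mobius_point(pixel_to_z(side), mobius_inverse(params))
  sr <- cx - Im(zsrc) * half
  sc <- cx + Re(zsrc) * half
  bad <- !is.finite(sr) | !is.finite(sc)
  sr[bad] <- -1e9
  sc[bad] <- -1e9
  warp_bilinear(pixels, matrix(sr, side, side), matrix(sc, side, side), fill)
}

#' Draw random Moebius parameters for augmentation
#'
#' Three fixed, non-collinear anchor points in the normalized image plane
#' are mapped to uniformly jittered copies of themselves and the
#' transformation through those correspondences is solved for. `jitter` is
#' expressed as a fraction of the image side (default 15%), so parameters
#' are resolution independent. Uses the current RNG stream.
#'
#' @param jitter maximum displacement of each anchor, as a fraction of the
#'   image side.
#' @return A [mobius_params()].
#' @export
sample_mobius_params <- function(jitter = 0.15) {
  zsrc <- complex(real = c(-0.5, 0.5, 0), imaginary = c(0, 0, 0.5))
  j <- 2 * jitter  # normalized units: side/2 is one unit
  repeat {
    w <- zsrc + complex(real = runif(3L, -j, j), imaginary = runif(3L, -j, j))
    p <- tryCatch(mobius_from_points(zsrc, w), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# Bilinear sampling of px at fractional source coordinates (sr, sc); the
# shared kernel behind all geometric warps in the package.
warp_bilinear <- function(px, sr, sc, fill) {
  H <- nrow(px)
  W <- ncol(px)
  eps <- 1e-6  # tolerate boundary coordinates perturbed by rounding
  inb <- sr >= 1 - eps & sr <= H + eps & sc >= 1 - eps & sc <= W + eps
  sr <- pmin(pmax(sr, 1), H)
  sc <- pmin(pmax(sc, 1), W)
  r0 <- floor(sr)
  c0 <- floor(sc)
  fr <- sr - r0
  fc <- sc - c0
  g <- function(r, c)
    px[cbind(pmin(pmax(as.vector(r), 1), H), pmin(pmax(as.vector(c), 1), W))]
  v <- (1 - fr) * (1 - fc) * g(r0, c0) + (1 - fr) * fc * g(r0, c0 + 1) +
    fr * (1 - fc) * g(r0 + 1, c0) + fr * fc * g(r0 + 1, c0 + 1)
  out <- ifelse(as.vector(inb), v, fill)
  matrix(out, nrow(sr), ncol(sr))
}
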