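#' @useDynLib stagernet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif sd prcomp kmeans predict var
#' @importFrom utils read.csv write.csv write.table head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Derive a stream of child seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Pixel matrices are (row, col) with row 1 at the top; EBImage stores
# transposed (x = column first), so every hand-off goes through these two.
as_ebimage <- function(px) EBImage::Image(t(px))
from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) d <- d[, , 1L]
  t(d)
}
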