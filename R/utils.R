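#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Per-frame RNG stream: stable under frame sampling, independent of call order.
frame_seed <- function(base_seed, frame_index) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(frame_index) * 104729) %%
               2147483647L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Polygon area by the shoelace formula
#'
#' Absolute area of a simple polygon given its ordered vertices; orientation
#' independent.
#'
#' @param xy two-column matrix of vertices (x, y) in order around the polygon.
#' @return Non-negative area in squared pixel units.
#' @export
polygon_area <- function(xy) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Bilinear interpolation of image values at continuous (x, y) coordinates.
# Pixel centers sit at integer coordinates; x indexes columns, y rows.
bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 1, w); y <- clamp(y, 1, h)
  x0 <- clamp(floor(x), 1, w - 1); y0 <- clamp(floor(y), 1, h - 1)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# Central-difference gradient magnitude sampled at continuous coordinates.
gradient_magnitude_at <- function(img, x, y) {
  gx <- (bilinear(img, x + 1, y) - bilinear(img, x - 1, y)) / 2
  gy <- (bilinear(img, x, y + 1) - bilinear(img, x, y - 1)) / 2
  sqrt(gx^2 + gy^2)
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end) of indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
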