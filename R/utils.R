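#' @keywords internal
"_PACKAGE"

## Small numerical helpers shared across the package.

# Trapezoid quadrature weights for an increasing grid (uniform or not).
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("trapezoid rule needs at least two grid points")
  dx <- diff(x)
  w <- numeric(n)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

# Definite trapezoid integral of y sampled on x.
trapz <- function(x, y) sum(trapz_weights(x) * y)

# Cumulative trapezoid integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-n] + y[-1L]) / 2))
}

#' Bilinear interpolation on a rectangular grid
#'
#' Interpolates a matrix of values sampled on the grid `x` (rows) by `y`
#' (columns) at arbitrary query points. Queries outside the grid rectangle are
#' clamped to the boundary (with a warning), which is the behaviour wanted for
#' density/cFDR surfaces whose support deliberately encloses the data.
#'
#' @param x Increasing numeric vector of row coordinates.
#' @param y Increasing numeric vector of column coordinates.
#' @param z Numeric matrix of dimension `length(x)` by `length(y)`.
#' @param xq,yq Numeric vectors of query coordinates (recycled to a common
#'   length).
#' @return Numeric vector of interpolated values; exact at grid nodes.
#' @export
bilinear_interpolate <- function(x, y, z, xq, yq) {
  if (anyNA(xq) || anyNA(yq)) stop("NaN/NA query coordinates in bilinear_interpolate")
  nq <- max(length(xq), length(yq))
  xq <- rep_len(xq, nq)
  yq <- rep_len(yq, nq)
  out_of_range <- xq < x[1L] | xq > x[length(x)] | yq < y[1L] | yq > y[length(y)]
  if (any(out_of_range)) {
    warning(sprintf("%d query point(s) outside the grid; clamped to the boundary",
                    sum(out_of_range)))
    xq <- pmin(pmax(xq, x[1L]), x[length(x)])
    yq <- pmin(pmax(yq, y[1L]), y[length(y)])
  }
  ix <- pmin(pmax(findInterval(xq, x), 1L), length(x) - 1L)
  iy <- pmin(pmax(findInterval(yq, y), 1L), length(y) - 1L)
  tx <- (xq - x[ix]) / (x[ix + 1L] - x[ix])
  ty <- (yq - y[iy]) / (y[iy + 1L] - y[iy])
  z00 <- z[cbind(ix, iy)]
  z10 <- z[cbind(ix + 1L, iy)]
  z01 <- z[cbind(ix, iy + 1L)]
  z11 <- z[cbind(ix + 1L, iy + 1L)]
  (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
}

# Validate a probability vector lies in (0, 1].
check_p <- function(p, what = "p") {
  if (length(p) == 0L) stop(sprintf("empty %s vector", what))
  if (anyNA(p) || any(!is.finite(p))) stop(sprintf("non-finite values in %s", what))
  if (any(p <= 0) || any(p > 1))
    stop(sprintf("%s values must lie in (0, 1]; offending rows: %s", what,
                 paste(utils::head(which(p <= 0 | p > 1), 5L), collapse = ", ")))
  invisible(TRUE)
}
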