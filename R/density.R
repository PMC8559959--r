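## Reflected bivariate kernel density estimation of (|Z|, Q).
##
## GWAS p-values from two-tailed tests are mapped to absolute Z-scores, which
## are bounded below by zero. A plain product-Gaussian KDE underestimates the
## density near that boundary, so the absolute Z-scores are mirrored onto the
## negative half-line (together with their covariate values) and the fitted
## mass at -z is folded back onto +z (Silverman's reflection technique).

#' Convert two-sided p-values to absolute Z-scores
#'
#' The absolute Z-score of a two-sided test, \eqn{|z| = -\Phi^{-1}(p/2)}, so
#' that \eqn{p = 2(1 - \Phi(|z|))}. Signs of GWAS Z-scores are arbitrary
#' (they depend on which allele is labelled the effect allele), so only the
#' magnitude is used throughout.
#'
#' @param p Numeric vector of p-values in (0, 1]. Zero is rejected: it would
#'   map to an infinite Z-score.
#' @return Numeric vector of absolute Z-scores (>= 0).
#' @export
p_to_abs_z <- function(p) {
  check_p(p)
  -stats::qnorm(p / 2)
}

#' Convert absolute Z-scores back to two-sided p-values
#' @param z Numeric vector of absolute Z-scores (>= 0).
#' @return Numeric vector of p-values, `2 * pnorm(-z)`.
#' @export
abs_z_to_p <- function(z) {
  if (any(z < 0)) stop("absolute Z-scores must be >= 0")
  2 * stats::pnorm(-z)
}

#' Normal-reference (rule-of-thumb) bandwidth
#'
#' Silverman's rule for a Gaussian kernel:
#' \eqn{1.06 \min(\hat\sigma, IQR/1.34) n^{-1/5}}. Assumes approximately
#' independent observations, which is why densities in this package are fitted
#' on a subset of LD-independent SNPs.
#'
#' @param x Numeric vector, length >= 10, with non-zero spread.
#' @return A single positive bandwidth.
#' @export
normal_reference_bandwidth <- function(x) {
  if (length(x) < 10L) stop("need at least 10 observations for a bandwidth")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in bandwidth input")
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(spread) || spread <= 0) stop("zero spread: bandwidth undefined")
  1.06 * spread * length(x)^(-1 / 5)
}

#' Support limits for the (|Z|, Q) density
#'
#' The Z axis runs from 0 to `max(1.1 * max(z_abs), 10)` so that p-values down
#' to ~1e-22 sit inside the grid. The covariate axis is widened by 5% of the
#' observed range on each side (total width 1.1 times the observed range) so
#' that the KDE support encloses all data and its integral can be
#' renormalised to one.
#'
#' @param z_abs Absolute Z-scores of all SNPs.
#' @param q Covariate values of all SNPs.
#' @return List with `z_max`, `q_low_support`, `q_high_support`.
#' @export
support_limits <- function(z_abs, q) {
  if (any(z_abs < 0)) stop("absolute Z-scores must be >= 0")
  if (anyNA(q) || any(!is.finite(q))) stop("non-finite covariate values")
  rng <- range(q)
  pad <- 0.05 * (rng[2L] - rng[1L])
  if (pad == 0) pad <- max(abs(rng[1L]), 1) * 0.05  # degenerate-range guard
  list(z_max = max(1.1 * max(z_abs), 10),
       q_low_support = rng[1L] - pad,
       q_high_support = rng[2L] + pad)
}

#' Fit the boundary-reflected bivariate KDE of (|Z|, Q)
#'
#' Fits a product-Gaussian-kernel density to the mirrored sample
#' \eqn{\{(\pm z_i, q_i)\}} and evaluates it on a rectangular grid over
#' \eqn{[0, z_{max}] \times [q_{low}, q_{high}]} with the mass at negative Z
#' folded back: \eqn{\hat f(x, y) = g(x, y) + g(-x, y)} where \eqn{g} is the
#' standard estimate on the 2n mirrored points. Each kernel is the normalised
#' bivariate product Gaussian \eqn{(2\pi\sigma_p\sigma_q)^{-1}
#' \exp\{-\frac12[((x-z_i)/\sigma_p)^2 + ((y-q_i)/\sigma_q)^2]\}}; the grid is
#' renormalised to unit trapezoidal mass after folding (truncation at `z_max`
#' loses a negligible sliver of mass).
#'
#' Bandwidths come from [normal_reference_bandwidth()] applied to the
#' unmirrored `z_abs` and to `q`; both should come from an (approximately)
#' LD-independent subset of SNPs so the iid bandwidth rule applies.
#'
#' @param z_abs Absolute Z-scores of the fitting subset (>= 0).
#' @param q Covariate values of the fitting subset, same length.
#' @param limits Optional support limits as returned by [support_limits()];
#'   computed from the fitting data when `NULL`. Covariate values must lie
#'   within the limits.
#' @param grid_nx,grid_ny Number of equally spaced grid nodes on the Z and
#'   covariate axes (default 501 each).
#' @return An object of class `"flexcfdr_grid"`: list with `x` (Z-axis nodes,
#'   starting at 0), `y` (covariate nodes), `f` (density matrix, `x` by `y`),
#'   `bandwidths` (list `sigma_p`, `sigma_q`) and `n_fit`.
#' @export
fit_reflected_kde <- function(z_abs, q, limits = NULL,
                              grid_nx = 501L, grid_ny = 501L) {
  n <- length(z_abs)
  if (length(q) != n) stop("z_abs and q must have the same length")
  if (n < 10L) stop("need at least 10 points to fit the KDE")
  if (any(z_abs < 0)) stop("absolute Z-scores must be >= 0")
  if (anyNA(q) || any(!is.finite(q))) stop("non-finite covariate values")
  if (grid_nx < 50L || grid_ny < 50L) stop("grid sizes must be at least 50")
  if (is.null(limits)) limits <- support_limits(z_abs, q)
  if (any(q < limits$q_low_support) || any(q > limits$q_high_support))
    stop("covariate values outside the stated support limits")

  # The rule-of-thumb is applied to the sample the KDE is actually fit to:
  # the mirrored {+-z} (whose spread, not the folded one, governs the
  # smoothness of the reflected fit) and the correspondingly duplicated q.
  sigma_p <- normal_reference_bandwidth(c(z_abs, -z_abs))
  sigma_q <- normal_reference_bandwidth(c(q, q))

  x <- seq(0, limits$z_max, length.out = grid_nx)
  y <- seq(limits$q_low_support, limits$q_high_support, length.out = grid_ny)

  # Separable kernels: f = (A %*% t(B)) / n with the Z-axis kernel already
  # folded (reflection), A[g, i] = phi((x_g - z_i)/s) + phi((x_g + z_i)/s).
  ax <- outer(x, z_abs, function(g, zi)
    stats::dnorm((g - zi) / sigma_p) + stats::dnorm((g + zi) / sigma_p)) / sigma_p
  by <- outer(y, q, function(g, qi) stats::dnorm((g - qi) / sigma_q)) / sigma_q
  f <- (ax %*% t(by)) / n

  # Renormalise to unit mass over the truncated rectangle.
  mass <- as.numeric(trapz_weights(x) %*% f %*% trapz_weights(y))
  if (!is.finite(mass) || mass <= 0) stop("degenerate KDE mass")
  f <- f / mass

  structure(list(x = x, y = y, f = f,
                 bandwidths = list(sigma_p = sigma_p, sigma_q = sigma_q),
                 n_fit = n),
            class = "flexcfdr_grid")
}

#' Joint upper-lower tail table of the fitted density
#'
#' Computes \eqn{T[i, j] = \Pr(|Z| \ge x_i, Q \le y_j)} by cumulative
#' trapezoidal integration of the density grid: the estimate of the
#' denominator of the cFDR estimator,
#' \eqn{\int_{-\infty}^{q}\int_{z_p}^{\infty} f(x, y)\,dx\,dy}.
#'
#' @param grid A `"flexcfdr_grid"` from [fit_reflected_kde()].
#' @return Matrix with the same dimensions as `grid$f`, non-increasing along
#'   rows (Z upward), non-decreasing along columns (covariate upward), with
#'   `T[1, ncol]` equal to 1 up to quadrature error.
#' @export
joint_tail_table <- function(grid) {
  stopifnot(inherits(grid, "flexcfdr_grid"))
  f <- grid$f
  nx <- length(grid$x); ny <- length(grid$y)
  # inner integral over y (columns), cumulative from y_min
  dy <- diff(grid$y)
  m <- f[, -ny, drop = FALSE] + f[, -1L, drop = FALSE]
  inner <- cbind(0, t(apply(sweep(m, 2L, dy / 2, "*"), 1L, cumsum)))
  # outer integral over x from x_i to x_max (reverse cumulative)
  dx <- diff(grid$x)
  a <- inner[-nx, , drop = FALSE] + inner[-1L, , drop = FALSE]
  seg <- sweep(a, 1L, dx / 2, "*")
  tail_x <- rbind(apply(seg[rev(seq_len(nx - 1L)), , drop = FALSE], 2L, cumsum)[rev(seq_len(nx - 1L)), , drop = FALSE], 0)
  pmin(pmax(tail_x, 0), 1 + 1e-3)
}
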