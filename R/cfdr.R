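## Core of the flexible conditional false discovery rate:
##   cfdr(p, q) = p * Pr(Q <= q | H0) / Pr(P <= p, Q <= q)
## with Pr(Q <= q | H0) obtained by weighting the joint (|Z|, Q) density by
## the local fdr, and each observed (p, q) pair mapped to a v-value: the
## probability under the null that a fresh pair falls inside the L-region
## (the set of points with estimated cFDR at most the observed level).

#' Left-censor a sparse covariate tail
#'
#' Replaces all covariate values below `q_low` by `q_low`, where `q_low` is
#' the left edge of the lowest covariate-grid cell containing at least
#' `gridp` data points. This stabilises the KDE in the sparse left tail;
#' the right tail needs no such treatment because the method only uses
#' cumulative densities there.
#'
#' @param q Covariate values (all SNPs, not just the fitting subset).
#' @param y_grid The covariate-axis grid nodes; cells are the intervals
#'   between consecutive nodes.
#' @param gridp Minimum number of points per cell deemed sufficient to
#'   estimate the density reliably (default 50).
#' @return List with `q` (censored values), `q_low`, and `n_censored`.
#' @export
left_censor <- function(q, y_grid, gridp = 50L) {
  if (gridp < 1L) stop("gridp must be at least 1")
  if (gridp > length(q))
    stop("gridp exceeds the number of data points; lower gridp or coarsen the grid")
  ncell <- length(y_grid) - 1L
  counts <- tabulate(pmin(pmax(findInterval(q, y_grid, rightmost.closed = TRUE), 1L),
                          ncell), nbins = ncell)
  first_dense <- which(counts >= gridp)[1L]
  if (is.na(first_dense))
    stop("no covariate grid cell reaches gridp points; lower gridp or coarsen the grid")
  q_low <- y_grid[first_dense]
  censored <- q < q_low
  q[censored] <- q_low
  list(q = q, q_low = q_low, n_censored = sum(censored))
}

#' Null covariate distribution from an fdr-weighted density
#'
#' Weights the joint density by the local fdr,
#' \eqn{g(x, y) = fdr(x)\,\hat f(x, y) \approx \Pr(Z = x, Q = y, H_0)},
#' and integrates: \eqn{f_{0q}(y) = \int g\,dx / \pi_0^{mass}} with
#' \eqn{\pi_0^{mass} = \int\int g\,dx\,dy \approx \Pr(H_0)}, and
#' \eqn{F_{0q}} the cumulative integral of \eqn{f_{0q}} renormalised to end
#' at one.
#'
#' @param grid A `"flexcfdr_grid"` density.
#' @param fdr_fit A `"flexcfdr_lfdr"` local fdr fit sharing the Z support.
#' @return List with `f0q`, `F0q` (vectors on `grid$y`) and `pi0_mass`.
#' @export
null_q_distribution <- function(grid, fdr_fit) {
  stopifnot(inherits(grid, "flexcfdr_grid"), inherits(fdr_fit, "flexcfdr_lfdr"))
  w <- evaluate_fdr(fdr_fit, grid$x)
  g <- grid$f * w  # recycles w down columns: g[i, j] = fdr(x_i) f[i, j]
  wx <- trapz_weights(grid$x)
  f0q <- as.numeric(wx %*% g)
  pi0_mass <- trapz(grid$y, f0q)
  if (!is.finite(pi0_mass) || pi0_mass < 1e-6)
    stop("degenerate null: fdr-weighted density mass is essentially zero")
  f0q <- f0q / pi0_mass
  F0q <- cumtrapz(grid$y, f0q)
  F0q <- F0q / F0q[length(F0q)]
  list(f0q = f0q, F0q = F0q, pi0_mass = pi0_mass)
}

#' Assemble the cFDR surface on the density grid
#'
#' At each node \eqn{(x_i, y_j)}:
#' \eqn{\widehat{cFDR} = p(x_i)\,F_{0q}(y_j)/T[i, j]} with
#' \eqn{p(x) = 2(1 - \Phi(x))} and `T` the joint tail table. Nodes whose
#' denominator falls below `floor` (empty grid corners) inherit the value of
#' the nearest valid node toward smaller Z. The surface is floored at 1e-300
#' but not capped at 1: values slightly above 1 are estimation noise around
#' the null value and are what separates the contours of near-null points.
#'
#' @param grid A `"flexcfdr_grid"` density.
#' @param joint_tail Matrix from [joint_tail_table()].
#' @param null_q List from [null_q_distribution()].
#' @param floor Denominator floor (default 1e-12).
#' @return Object of class `"flexcfdr_surface"`: list with `x`, `y`, `cfdr`
#'   matrix, `f0q`, `F0q`, `pi0_mass`, `joint_tail`.
#' @export
cfdr_surface <- function(grid, joint_tail, null_q, floor = 1e-12) {
  stopifnot(inherits(grid, "flexcfdr_grid"))
  if (!all(dim(joint_tail) == dim(grid$f))) stop("joint_tail/grid dimension mismatch")
  p_x <- abs_z_to_p(grid$x)
  num <- outer(p_x, null_q$F0q)
  denom <- joint_tail
  bad <- denom < floor
  cfdr <- num / pmax(denom, floor)
  if (any(bad)) {
    # carry the last valid value downward in each column (toward larger Z)
    for (j in seq_along(grid$y)) {
      col_bad <- bad[, j]
      if (any(col_bad)) {
        v <- cfdr[, j]
        idx <- which(!col_bad)
        if (length(idx) == 0L) { cfdr[, j] <- 1; next }
        # nearest valid node toward smaller x
        filled <- v
        pos <- findInterval(which(col_bad), idx)
        pos[pos == 0L] <- 1L
        filled[col_bad] <- v[idx[pos]]
        cfdr[, j] <- filled
      }
    }
  }
  # floor only: values above 1 are legitimate noise around the null value 1
  # and are what separates the contours of near-null points — capping them
  # would tie half the surface at exactly 1 and destroy null calibration
  cfdr <- pmax(cfdr, 1e-300)
  # the rejection-region family is built from the running minimum along Z
  # (rightmost-filled L-regions); levels are read off the same monotone
  # surface so that the v-value is an exact probability integral transform
  cfdr_mono <- apply(cfdr, 2L, cummin)
  structure(list(x = grid$x, y = grid$y, cfdr = cfdr, cfdr_mono = cfdr_mono,
                 f0q = null_q$f0q, F0q = null_q$F0q,
                 pi0_mass = null_q$pi0_mass, joint_tail = joint_tail),
            class = "flexcfdr_surface")
}

#' cFDR level at an observed (p, q) pair
#'
#' Bilinear interpolation of the cFDR surface at `(-qnorm(p/2), q)`. The
#' level is read off the x-monotonicized surface (running minimum along the
#' Z axis): the L-region at a level is rightmost-filled per covariate row,
#' so the region family is generated by the monotone surface, and reading
#' the level off the same surface makes the v-value an exact probability
#' integral transform (uniform under the null). Where the raw surface is
#' locally monotone in Z the two coincide.
#'
#' @param surface A `"flexcfdr_surface"`.
#' @param p,q Numeric vectors (recycled to a common length); `p` in (0, 1],
#'   `q` expected inside the covariate support (clamped otherwise).
#' @return Numeric vector of cFDR levels (positive; may slightly exceed 1).
#' @export
point_level <- function(surface, p, q) {
  stopifnot(inherits(surface, "flexcfdr_surface"))
  check_p(p)
  z <- p_to_abs_z(p)
  z <- pmin(z, surface$x[length(surface$x)])  # beyond-grid p: clamp, cfdr only shrinks
  bilinear_interpolate(surface$x, surface$y, surface$cfdr_mono, z, q)
}

# Rightmost-crossing p-boundaries for a batch of levels.
# Returns a length(y) x length(levels) matrix P_L with
# P_L[j, s] = largest p such that the row-j prefix of the surface crosses
# below levels[s], linearly interpolated in p between the bracketing nodes.
l_curve_matrix <- function(surface, levels) {
  cf <- surface$cfdr
  mono <- surface$cfdr_mono
  nx <- length(surface$x)
  ny <- length(surface$y)
  pgrid <- abs_z_to_p(surface$x)          # decreasing from 1
  ord <- order(levels)
  lev_sorted <- levels[ord]
  out <- matrix(0, nrow = ny, ncol = length(levels))
  for (j in seq_len(ny)) {
    pm <- mono[, j]
    # k = number of leading nodes with running min > level; the first raw
    # crossing is at k+1 (running min > level means every raw value so far
    # exceeds the level too)
    k <- findInterval(-lev_sorted, -pm, left.open = TRUE)
    pl <- numeric(length(lev_sorted))
    at_top <- k == 0L          # node at x = 0 already qualifies -> whole strip
    none <- k == nx            # no node qualifies -> empty row
    mid <- !at_top & !none
    pl[at_top] <- 1
    pl[none] <- 0
    if (any(mid)) {
      km <- k[mid]
      c1 <- cf[cbind(km, j)]       # raw bracketing nodes
      c2 <- cf[cbind(km + 1L, j)]
      tt <- (c1 - lev_sorted[mid]) / (c1 - c2)
      tt[!is.finite(tt)] <- 1
      pl[mid] <- pgrid[km] + tt * (pgrid[km + 1L] - pgrid[km])
    }
    out[j, ord] <- pl
  }
  out
}

#' L-curve (rightmost rejection boundary) at a cFDR level
#'
#' For each covariate row the Z axis is scanned from 0 upward (p from 1
#' downward) and the boundary is the p of the first node whose running cFDR
#' minimum drops to `level` or below, linearly interpolated in p between the
#' bracketing nodes. Rows whose node at Z = 0 already qualifies get boundary
#' 1 (the whole strip); rows that never qualify get 0. Taking the first
#' crossing of the running minimum makes the L-region "rightmost-filled":
#' non-monotone dips further right cannot exclude points with larger p than
#' an already-qualifying point.
#'
#' @param surface A `"flexcfdr_surface"`.
#' @param level A single cFDR level in (0, 1].
#' @return Object of class `"flexcfdr_lcurve"`: list with `level` and `p_L`
#'   (vector over `surface$y`).
#' @export
l_curve <- function(surface, level) {
  stopifnot(inherits(surface, "flexcfdr_surface"), length(level) == 1L,
            level > 0, level <= 1)
  structure(list(level = level,
                 p_L = as.numeric(l_curve_matrix(surface, level))),
            class = "flexcfdr_lcurve")
}

#' Integrate the null density over an L-region: the v-value
#'
#' Because \eqn{P \mid H_0} is uniform, the inner p-integral over the region
#' \eqn{\{(p, q): p \le p_L(q)\}} is exactly \eqn{p_L(q)}, so
#' \eqn{v = \int p_L(y) f_{0q}(y)\,dy} by the trapezoid rule over the
#' covariate grid (with \eqn{f_{0q}} normalised to unit trapezoidal mass, so
#' a constant boundary \eqn{p_L \equiv c} yields exactly \eqn{v = c}).
#'
#' @param surface A `"flexcfdr_surface"`.
#' @param curve A `"flexcfdr_lcurve"` on the same covariate axis.
#' @return A single v-value in (0, 1] (floored at 1e-300).
#' @export
v_value <- function(surface, curve) {
  stopifnot(inherits(surface, "flexcfdr_surface"), inherits(curve, "flexcfdr_lcurve"))
  if (length(curve$p_L) != length(surface$y)) stop("curve/surface axis mismatch")
  w <- trapz_weights(surface$y) * surface$f0q
  w <- w / sum(w)
  v <- sum(w * curve$p_L)
  min(max(v, 1e-300), 1)
}

#' Spline correction of v-values in jointly sparse regions
#'
#' Where (p, q) are jointly sparse a v-value can sit far off the overall
#' trend, artifactually inflating (or deflating) the evidence relative to p.
#' A cubic regression spline with 5 interior knots at the 1/6, ..., 5/6
#' quantiles of `q` is fitted once to \eqn{r = \log_{10}(v/p)} against `q`;
#' points with \eqn{|r - s(q)| >} `dist_thr` are mapped back to the spline:
#' \eqn{v \leftarrow p\,10^{s(q)}}, clamped to (0, 1].
#'
#' @param p,q,v Aligned numeric vectors.
#' @param dist_thr Distance threshold on the log10 ratio scale (default 0.5).
#' @param inflation_only If `TRUE`, only points above the spline (v inflated
#'   towards significance, r below it since smaller v means more significant)
#'   are corrected; default `FALSE` corrects both directions of deviation.
#' @return List with `v` (corrected values) and `corrected` (logical flags).
#' @export
spline_correct <- function(p, q, v, dist_thr = 0.5, inflation_only = FALSE) {
  if (dist_thr <= 0) stop("dist_thr must be positive")
  n <- length(v)
  if (length(p) != n || length(q) != n) stop("p, q, v must be aligned")
  if (length(unique(q)) < 7L) {
    warning("fewer than 7 distinct covariate values; spline correction skipped")
    return(list(v = v, corrected = rep(FALSE, n)))
  }
  r <- log10(v / p)
  knots <- stats::quantile(q, probs = (1:5) / 6, names = FALSE, type = 7)
  knots <- unique(knots[knots > min(q) & knots < max(q)])
  basis <- if (length(knots) >= 1L) {
    splines::bs(q, knots = knots, degree = 3L)
  } else {
    splines::bs(q, df = 4L, degree = 3L)
  }
  fit <- stats::lm.fit(cbind(1, basis), r)
  s <- r - fit$residuals
  dev <- r - s
  flag <- if (inflation_only) dev < -dist_thr else abs(dev) > dist_thr
  flag[is.na(flag)] <- FALSE
  v_out <- v
  v_out[flag] <- pmin(pmax(p[flag] * 10^(s[flag]), 1e-300), 1)
  list(v = v_out, corrected = flag)
}

#' Flexible cFDR: map p-value/covariate pairs to v-values
#'
#' The full estimator pipeline: optional covariate sign alignment (so that
#' small covariate values are enriched for small p-values), support limits,
#' left-censoring of the sparse covariate tail, boundary-reflected bivariate
#' KDE of (|Z|, Q) on the independent subset, local fdr fit, fdr-weighted
#' null covariate distribution, joint tail table, cFDR surface, and per-SNP
#' L-region integration to v-values with a final spline correction for
#' jointly sparse regions. SNPs sharing a cFDR level share an L-curve
#' (levels are deduplicated before curve construction).
#'
#' @param p P-values in (0, 1] for the principal trait (or v-values from a
#'   previous iteration).
#' @param q Continuous auxiliary covariate, same length, finite.
#' @param indep Logical mask (or integer indices) of the approximately
#'   LD-independent subset used to fit densities; default all SNPs.
#' @param align_sign Reverse the covariate sign if its Pearson correlation
#'   with p over the independent subset is strictly negative (default TRUE).
#' @param gridp Left-censoring count threshold (default 50).
#' @param dist_thr Spline-correction distance threshold (default 0.5).
#' @param grid_nx,grid_ny Density grid sizes (default 501 each).
#' @param lfdr_bins,lfdr_df Local fdr histogram bins and spline df
#'   (defaults 120 and 7).
#' @param inflation_only Restrict the spline correction to the inflation
#'   side (default FALSE).
#' @param keep_fit Attach the fitted surface and intermediate objects as
#'   attribute `"fit"` (default FALSE).
#' @return A data.frame with one row per SNP: `p`, `q_used` (aligned and
#'   censored covariate), `v`, `level` (cFDR at the pair), `censored` and
#'   `corrected` flags. Attribute `"flipped"` records whether the covariate
#'   sign was reversed.
#' @export
flexible_cfdr <- function(p, q, indep = NULL, align_sign = TRUE,
                          gridp = 50L, dist_thr = 0.5,
                          grid_nx = 501L, grid_ny = 501L,
                          lfdr_bins = 120L, lfdr_df = 7L,
                          inflation_only = FALSE, keep_fit = FALSE) {
  m <- length(p)
  if (length(q) != m) stop("p and q must have the same length")
  if (m < 2L) stop("cannot fit a cFDR model to fewer than 2 SNPs")
  check_p(p)
  if (anyNA(q) || any(!is.finite(q))) stop("non-finite covariate values")
  if (is.null(indep)) indep <- rep(TRUE, m)
  if (is.numeric(indep)) indep <- seq_len(m) %in% indep
  if (!any(indep)) stop("independent subset is empty")

  flipped <- FALSE
  if (align_sign) {
    if (stats::sd(q[indep]) == 0) stop("covariate has zero variance on the independent subset")
    if (stats::cor(p[indep], q[indep]) < 0) {
      q <- -q
      flipped <- TRUE
    }
  }

  z <- p_to_abs_z(p)
  limits <- support_limits(z, q)
  # Censoring counts points per cell of a bandwidth-granularity grid, not of
  # the (arbitrarily fine) evaluation grid: the count measures local data
  # support for the kernel, so the cell width that makes "gridp points" a
  # meaningful reliability criterion is one kernel bandwidth.
  sigma_cens <- normal_reference_bandwidth(q[indep])
  n_cells <- max(2L, ceiling((limits$q_high_support - limits$q_low_support) /
                               sigma_cens))
  cens_grid <- seq(limits$q_low_support, limits$q_high_support,
                   length.out = n_cells + 1L)
  cens <- left_censor(q, cens_grid, gridp = gridp)
  q_used <- cens$q
  censored <- q != q_used

  kde <- fit_reflected_kde(z[indep], q_used[indep], limits = limits,
                           grid_nx = grid_nx, grid_ny = grid_ny)
  lfdr <- fit_local_fdr(z[indep], n_bins = lfdr_bins, spline_df = lfdr_df,
                        z_max = limits$z_max)
  nq <- null_q_distribution(kde, lfdr)
  tails <- joint_tail_table(kde)
  surface <- cfdr_surface(kde, tails, nq)

  levels <- point_level(surface, p, q_used)
  uniq <- unique(levels)
  pl <- l_curve_matrix(surface, uniq)
  w <- trapz_weights(surface$y) * surface$f0q
  w <- w / sum(w)
  v_uniq <- pmin(pmax(as.numeric(w %*% pl), 1e-300), 1)
  v <- v_uniq[match(levels, uniq)]
  if (any(!is.finite(v)))
    stop("non-finite v-value produced; inspect the cFDR surface near the offending levels")

  corr <- spline_correct(p, q_used, v, dist_thr = dist_thr,
                         inflation_only = inflation_only)

  out <- data.frame(p = p, q_used = q_used, v = corr$v, level = levels,
                    censored = censored, corrected = corr$corrected)
  attr(out, "flipped") <- flipped
  attr(out, "q_low") <- cens$q_low
  attr(out, "n_censored") <- cens$n_censored
  if (keep_fit)
    attr(out, "fit") <- list(surface = surface, kde = kde, lfdr = lfdr,
                             limits = limits)
  out
}
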