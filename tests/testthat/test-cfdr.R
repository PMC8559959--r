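flat_lfdr <- function(z_max) {
  zg <- seq(-z_max, z_max, length.out = 201)
  structure(list(z_grid = zg, f_marginal = dnorm(zg), pi0 = 1,
                 fdr_curve = rep(1, 201), n = 1000),
            class = "flexcfdr_lfdr")
}

test_that("left-censoring moves only points left of the first dense cell", {
  # dense uniform covariate: nothing to censor
  set.seed(20)
  q <- runif(100000)
  grid <- seq(0, 1, length.out = 501)
  res <- left_censor(q, grid, gridp = 50)
  expect_equal(res$q_low, 0)
  expect_equal(res$n_censored, 0)
  expect_equal(res$q, q)

  # constructed outliers: 10 points far left of 10,000 dense points
  set.seed(21)
  q2 <- c(rep(-10, 10), runif(10000))
  grid2 <- seq(-10.5, 1.5, length.out = 241)  # cell width 0.05
  counts <- tabulate(findInterval(q2, grid2, rightmost.closed = TRUE),
                     nbins = 240)
  expected_low <- grid2[which(counts >= 50)[1]]
  res2 <- left_censor(q2, grid2, gridp = 50)
  expect_equal(res2$q_low, expected_low)
  expect_equal(sum(res2$q == expected_low), res2$n_censored)
  expect_gte(res2$n_censored, 10)  # at least the 10 outliers
  expect_true(all(res2$q >= expected_low))

  expect_error(left_censor(runif(10), seq(0, 1, 0.1), gridp = 50), "exceeds")
  # 100 points spread over 100 cells: no cell can reach 50
  expect_error(left_censor(runif(100), seq(0, 1, 0.01), gridp = 50),
               "no covariate grid cell")
})

test_that("a flat fdr makes the null covariate density the plain marginal", {
  set.seed(22)
  z <- abs(rnorm(5000)); q <- rnorm(5000)
  g <- fit_reflected_kde(z, q, grid_nx = 101, grid_ny = 101)
  nq <- null_q_distribution(g, flat_lfdr(max(g$x)))
  marg <- as.numeric(flexcfdr:::trapz_weights(g$x) %*% g$f)
  expect_equal(nq$f0q, marg / flexcfdr:::trapz(g$y, marg), tolerance = 1e-10)
  expect_equal(nq$pi0_mass, 1, tolerance = 1e-3)
  expect_true(all(diff(nq$F0q) >= -1e-12))
  expect_equal(nq$F0q[length(nq$F0q)], 1)
})

test_that("with signal in p but independent q, F0q tracks the covariate ECDF", {
  set.seed(23)
  m <- 10000
  z <- abs(c(rnorm(m - 500), rnorm(500, 4, 1)))
  q <- rmix_bimodal(m)
  g <- fit_reflected_kde(z, q, grid_nx = 201, grid_ny = 201)
  lf <- fit_local_fdr(z, z_max = max(g$x))
  nq <- null_q_distribution(g, lf)
  ec <- ecdf(q)
  expect_lt(max(abs(nq$F0q - ec(g$y))), 0.05)
  expect_lte(nq$pi0_mass, 1 + 1e-6)
})

test_that("cFDR surface is one at the (p=1, q=max) corner and near one under the null", {
  set.seed(24)
  m <- 8000
  z <- abs(rnorm(m)); q <- rnorm(m)
  g <- fit_reflected_kde(z, q, grid_nx = 151, grid_ny = 151)
  lf <- fit_local_fdr(z, z_max = max(g$x))
  nq <- null_q_distribution(g, lf)
  s <- cfdr_surface(g, joint_tail_table(g), nq)
  ny <- length(s$y)
  expect_equal(s$cfdr[1, ny], 1, tolerance = 1e-3)
  bulk <- s$joint_tail >= 0.01
  expect_gte(median(s$cfdr[bulk]), 0.8)
  expect_lte(median(s$cfdr[bulk]), 1.05)
})

test_that("an uninformative covariate cancels out of the surface", {
  # signal in p keeps the Z tail populated; q independent of p
  set.seed(124)
  m <- 10000
  z <- abs(c(rnorm(m - 500), rnorm(500, 4, 1.5)))
  q <- rnorm(m)
  g <- fit_reflected_kde(z, q, grid_nx = 151, grid_ny = 151)
  lf <- fit_local_fdr(z, z_max = max(g$x))
  nq <- null_q_distribution(g, lf)
  s <- cfdr_surface(g, joint_tail_table(g), nq)
  # at fixed Z inside the populated range, little variation across q within
  # the central covariate mass
  sel <- s$F0q > 0.1 & s$F0q < 0.9
  for (zq in c(1, 2, 3)) {
    i <- which.min(abs(s$x - zq))
    row <- s$cfdr[i, sel]
    expect_lt((max(row) - min(row)) / median(row), 0.1)
  }
})

test_that("point levels agree with direct evaluation of the estimator ratio", {
  set.seed(25)
  m <- 10000
  z <- abs(c(rnorm(m - 1000), rnorm(1000, 3.5, 1.5)))
  q <- rnorm(m) - (z > 3) * 1.5  # informative covariate, monotone surface
  g <- fit_reflected_kde(z, q, grid_nx = 501, grid_ny = 501)
  lf <- fit_local_fdr(z, z_max = max(g$x))
  nq <- null_q_distribution(g, lf)
  tt <- joint_tail_table(g)
  s <- cfdr_surface(g, tt, nq)
  # 50 random query points in the populated part of the plane
  idx <- sample(which(z > 0.5 & z < 4), 50)
  lev <- point_level(s, abs_z_to_p(z[idx]), q[idx])
  # direct recomputation of p * F0q / T by interpolating the three integrals
  dir_F <- approx(s$y, s$F0q, q[idx])$y
  dir_T <- bilinear_interpolate(s$x, s$y, tt, z[idx], q[idx])
  direct <- abs_z_to_p(z[idx]) * dir_F / dir_T
  expect_lt(median(abs(lev / direct - 1)), 0.02)
  expect_lt(max(abs(lev / direct - 1)), 0.10)
  # node-coincident query returns the stored value
  expect_equal(point_level(s, abs_z_to_p(s$x[40]), s$y[60]),
               s$cfdr_mono[40, 60], tolerance = 1e-9)
  # the (p=1, q=max) corner
  expect_equal(point_level(s, 1, max(s$y)), 1, tolerance = 1e-3)
})

test_that("L-curves take the rightmost crossing and nest with the level", {
  x <- seq(0, 8, length.out = 6)
  y <- seq(-1, 1, length.out = 3)
  # one non-monotone row: dips below 0.5, rises, dips again
  row <- c(1.2, 0.4, 0.8, 0.9, 0.3, 0.2)
  cf <- cbind(row, rev(row) * 0 + 0.9, seq(1.1, 0.1, length.out = 6))
  s <- make_surface(x, y, cf)
  cur <- l_curve(s, 0.5)
  expect_equal(cur$p_L, oracle_p_l(s, 0.5))
  # the rightmost crossing of row 1 sits between nodes 1 and 2
  pg <- 2 * pnorm(-x)
  expect_equal(cur$p_L[1], pg[1] + (1.2 - 0.5) / (1.2 - 0.4) * (pg[2] - pg[1]))
  # level covering the whole surface -> whole strip
  expect_equal(l_curve(make_surface(x, y, cf * 0 + 0.7), 1)$p_L, rep(1, 3))
  # level below the minimum -> empty region
  expect_equal(l_curve(s, 0.05)$p_L, rep(0, 3))
  # nesting: p_L monotone in the level, hence v monotone
  levels <- c(0.2, 0.35, 0.5, 0.8)
  pls <- sapply(levels, function(a) l_curve(s, a)$p_L)
  expect_true(all(diff(t(pls)) >= -1e-12))
})

test_that("v-values integrate the null covariate density over the L-region", {
  x <- seq(0, 8, length.out = 20)
  y <- seq(-2, 2, length.out = 15)
  s <- make_surface(x, y, matrix(0.9, 20, 15),
                    f0q = dnorm(seq(-2, 2, length.out = 15)))
  # constant boundary c integrates to exactly c
  cur <- structure(list(level = 0.5, p_L = rep(0.37, 15)),
                   class = "flexcfdr_lcurve")
  expect_equal(v_value(s, cur), 0.37)
  cur1 <- structure(list(level = 1, p_L = rep(1, 15)), class = "flexcfdr_lcurve")
  expect_equal(v_value(s, cur1), 1)
})

test_that("fast-path v equals the brute-force region integral on random surfaces", {
  set.seed(26)
  for (rep in 1:4) {
    nx <- 40; ny <- 30
    x <- seq(0, 8, length.out = nx)
    y <- seq(-3, 3, length.out = ny)
    # smooth random positive surface, roughly decreasing in z
    base <- outer(exp(-0.3 * x), rep(1, ny))
    noise <- matrix(exp(0.5 * rnorm(nx * ny)), nx, ny)
    noise <- (noise[, c(1, 1:(ny - 1))] + noise + noise[, c(2:ny, ny)]) / 3
    cf <- pmin(base * noise + 0.02, 1.5)
    f0q <- abs(rnorm(ny)) + 0.1
    s <- make_surface(x, y, cf, f0q = f0q)
    levels <- runif(50, min(cf), 1)
    pl_fast <- flexcfdr:::l_curve_matrix(s, levels)
    w <- flexcfdr:::trapz_weights(y) * s$f0q
    w <- w / sum(w)
    v_fast <- pmin(pmax(as.numeric(w %*% pl_fast), 1e-300), 1)
    v_slow <- vapply(levels, function(a) oracle_v(s, oracle_p_l(s, a)),
                     numeric(1))
    expect_equal(v_fast, v_slow, tolerance = 1e-6)
  }
})

test_that("spline correction maps only outlying ratios back to the trend", {
  set.seed(27)
  n <- 300
  p <- runif(n, 1e-4, 1)
  q <- runif(n)
  v <- p  # perfect agreement: nothing to correct
  res <- spline_correct(p, q, v, dist_thr = 0.5)
  expect_equal(res$v, v)
  expect_false(any(res$corrected))

  # one constructed outlier with log10(v/p) = 1
  p[7] <- 0.01
  v2 <- p
  v2[7] <- p[7] * 10
  res2 <- spline_correct(p, q, v2, dist_thr = 0.5)
  expect_true(res2$corrected[7])
  expect_equal(sum(res2$corrected), 1)
  # oracle: same basis fitted independently
  r <- log10(v2 / p)
  kn <- quantile(q, (1:5) / 6, names = FALSE)
  fit <- lm(r ~ splines::bs(q, knots = kn, degree = 3))
  s_hat <- fitted(fit)
  expect_equal(res2$v[7], min(max(p[7] * 10^s_hat[7], 1e-300), 1),
               tolerance = 1e-8)
  expect_true(all(res2$v <= 1))

  # degenerate covariate: skipped with a warning
  expect_warning(res3 <- spline_correct(p, rep(1:3, each = 100), v2),
                 "skipped")
  expect_equal(res3$v, v2)
})

test_that("flexible_cfdr rejects degenerate inputs", {
  expect_error(flexible_cfdr(0.5, 1), "fewer than 2")
  expect_error(flexible_cfdr(c(0.5, 0), c(1, 2)), "\\(0, 1\\]")
  expect_error(flexible_cfdr(runif(100), rep(2, 100)), "zero variance")
  expect_error(flexible_cfdr(runif(100), c(NA, runif(99))), "non-finite")
})

test_that("an informative covariate shrinks v below p for true signals", {
  set.seed(28)
  m <- 4000
  is_sig <- seq_len(m) <= 300
  z <- abs(ifelse(is_sig, rnorm(m, 5, 1), rnorm(m)))
  p <- abs_z_to_p(z)
  # strongly informative: small q marks signals (positive orientation)
  q <- -z + rnorm(m, 0, 0.5)
  res <- flexible_cfdr(p, q, grid_nx = 201, grid_ny = 201)
  expect_false(attr(res, "flipped"))
  expect_lt(mean(res$v[is_sig]), mean(p[is_sig]))
  # reversed covariate gets flipped back to the same orientation
  res2 <- flexible_cfdr(p, -q, grid_nx = 201, grid_ny = 201)
  expect_true(attr(res2, "flipped"))
  expect_lt(mean(res2$v[is_sig]), mean(p[is_sig]))
})

test_that("row order and v finiteness are preserved through the pipeline", {
  set.seed(29)
  m <- 3000
  p <- runif(m)
  q <- rmix_bimodal(m)
  res <- flexible_cfdr(p, q, grid_nx = 151, grid_ny = 151)
  expect_equal(nrow(res), m)
  expect_equal(res$p, p)
  expect_true(all(is.finite(res$v)))
  expect_true(all(res$v > 0 & res$v <= 1))
})
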