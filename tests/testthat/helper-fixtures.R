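# Shared fixture builders. Everything is generated in code at test time.

# scenario-C style bimodal covariate, independent of p
rmix_bimodal <- function(m) {
  comp <- stats::runif(m) < 0.5
  ifelse(comp, stats::rnorm(m, -2, 0.5), stats::rnorm(m, 3, 2))
}

# write a small summary-statistic TSV and return its path
write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# assemble a cFDR surface object directly from a raw cfdr matrix (tests of
# the L-curve / v-value machinery on constructed surfaces)
make_surface <- function(x, y, cfdr, f0q = NULL) {
  if (is.null(f0q)) f0q <- rep(1 / diff(range(y)), length(y))
  w <- diff(y)
  F0q <- c(0, cumsum(w * (f0q[-length(f0q)] + f0q[-1]) / 2))
  F0q <- F0q / F0q[length(F0q)]
  structure(list(x = x, y = y, cfdr = cfdr,
                 cfdr_mono = apply(cfdr, 2, cummin),
                 f0q = f0q, F0q = F0q, pi0_mass = 1,
                 joint_tail = matrix(1, length(x), length(y))),
            class = "flexcfdr_surface")
}

# independent brute-force rightmost-crossing boundary for one level:
# plain double loop over the RAW surface, first node (scanning from p = 1
# downward) at or below the level, linearly interpolated in p
oracle_p_l <- function(surface, level) {
  cf <- surface$cfdr
  pgrid <- 2 * stats::pnorm(-surface$x)
  nx <- length(surface$x)
  out <- numeric(length(surface$y))
  for (j in seq_along(surface$y)) {
    hit <- NA_integer_
    for (i in seq_len(nx)) {
      if (cf[i, j] <= level) { hit <- i; break }
    }
    if (is.na(hit)) {
      out[j] <- 0
    } else if (hit == 1L) {
      out[j] <- 1
    } else {
      c1 <- cf[hit - 1L, j]; c2 <- cf[hit, j]
      tt <- (c1 - level) / (c1 - c2)
      out[j] <- pgrid[hit - 1L] + tt * (pgrid[hit] - pgrid[hit - 1L])
    }
  }
  out
}

# independent v integral given a boundary vector
oracle_v <- function(surface, p_l) {
  w <- flexcfdr:::trapz_weights(surface$y) * surface$f0q
  w <- w / sum(w)
  min(max(sum(w * p_l), 1e-300), 1)
}
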