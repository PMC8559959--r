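## Reading and validating GWAS summary-statistic tables, covariate
## orientation, MAF matching of the density-fitting subset, and the
## iterative pipeline driver.

#' Read a GWAS summary-statistic table
#'
#' Reads a tab-separated file with a header row and maps its columns onto the
#' fields the pipeline needs. P-values must lie in (0, 1] (a p-value of zero
#' has no finite Z-score) and covariates must be finite.
#'
#' @param path Path to a tab-separated file with a header.
#' @param cols Named list mapping fields to column names. Recognised fields:
#'   `snp_id`, `chrom`, `pos`, `p` (all required), `q` (required; may name
#'   several covariate columns), `maf` and `indep` (optional).
#' @return A data.frame with standardised columns `snp_id`, `chrom`, `pos`,
#'   `p`, the covariate columns under their original names, and optionally
#'   `maf` and `indep` (logical). Attribute `"q_cols"` lists the covariate
#'   column names.
#' @export
read_summary_table <- function(path,
                               cols = list(snp_id = "snp_id", chrom = "chrom",
                                           pos = "pos", p = "p", q = "q")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(cols$snp_id, cols$chrom, cols$pos, cols$p, cols$q,
                cols$maf, cols$indep)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop(sprintf("mapped column(s) not present in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))

  out <- data.frame(snp_id = as.character(raw[[cols$snp_id]]),
                    chrom = as.character(raw[[cols$chrom]]),
                    pos = as.integer(raw[[cols$pos]]),
                    p = as.numeric(raw[[cols$p]]),
                    stringsAsFactors = FALSE)
  bad_p <- which(!is.finite(out$p) | out$p <= 0 | out$p > 1)
  if (length(bad_p) > 0L)
    stop(sprintf("p-values outside (0, 1] (or missing) at row(s): %s",
                 paste(utils::head(bad_p, 10L), collapse = ", ")))
  for (qc in cols$q) {
    qv <- suppressWarnings(as.numeric(raw[[qc]]))
    bad_q <- which(!is.finite(qv))
    if (length(bad_q) > 0L)
      stop(sprintf("non-finite covariate '%s' at row(s): %s", qc,
                   paste(utils::head(bad_q, 10L), collapse = ", ")))
    out[[qc]] <- qv
  }
  if (!is.null(cols$maf)) {
    out$maf <- suppressWarnings(as.numeric(raw[[cols$maf]]))
    ok <- is.na(out$maf) | (out$maf > 0 & out$maf <= 0.5)
    if (!all(ok))
      stop(sprintf("MAF values outside (0, 0.5] at row(s): %s",
                   paste(utils::head(which(!ok), 10L), collapse = ", ")))
  }
  if (!is.null(cols$indep)) {
    iv <- raw[[cols$indep]]
    out$indep <- if (is.logical(iv)) iv else as.logical(as.integer(iv))
    if (anyNA(out$indep)) stop("independence flag column contains missing values")
    if (!any(out$indep)) stop("no record is flagged as independent")
  }
  attr(out, "q_cols") <- cols$q
  out
}

#' Align covariate orientation with the p-values
#'
#' The cFDR estimator assumes positive stochastic monotonicity: SNPs with
#' smaller covariate values should be enriched for smaller p-values. If the
#' Pearson correlation of (p, q) over the independent subset is strictly
#' negative the covariate sign is reversed; a correlation of exactly zero or
#' positive leaves it unchanged.
#'
#' @param table Summary table (data.frame with a `p` column; optional logical
#'   `indep` column restricting the correlation estimate).
#' @param q_col Name of the covariate column to align.
#' @return List with `table` (covariate possibly negated) and `flipped`.
#' @export
align_covariate_sign <- function(table, q_col) {
  if (nrow(table) < 3L) stop("need at least 3 records to estimate a correlation")
  if (!q_col %in% names(table)) stop(sprintf("no column '%s' in table", q_col))
  mask <- if (!is.null(table$indep)) table$indep else rep(TRUE, nrow(table))
  q <- table[[q_col]][mask]
  if (stats::sd(q) == 0)
    stop(sprintf("covariate '%s' has zero variance: it carries no information", q_col))
  flipped <- stats::cor(table$p[mask], q) < 0
  if (flipped) table[[q_col]] <- -table[[q_col]]
  list(table = table, flipped = flipped)
}

#' MAF-match the independent subset to the full table
#'
#' LD-independence weights and GWAS p-values are both confounded by minor
#' allele frequency: rarer SNPs are over-represented among independent SNPs
#' and have larger p-values on average, which would bias the density fit.
#' The MAF range is split into `n_bins` equal-probability bins of the FULL
#' table's MAF distribution and the independent subset is down-sampled
#' (without replacement) within each bin so that its bin proportions match
#' the full table's. Missing MAFs are first imputed by sampling from the
#' empirical distribution of the non-missing values.
#'
#' @param table Summary table with `maf` (possibly with NAs) and logical
#'   `indep` columns.
#' @param n_bins Number of equal-probability MAF bins (default 50).
#' @param seed Optional integer seed for the imputation and down-sampling.
#' @return Logical mask over the rows of `table`; a subset of `indep`.
#' @export
maf_match_independent_subset <- function(table, n_bins = 50L, seed = NULL) {
  if (is.null(table$maf)) stop("no MAF column supplied")
  if (is.null(table$indep)) stop("no independence flag column supplied")
  if (!is.null(seed)) set.seed(seed)
  maf <- table$maf
  obs <- maf[!is.na(maf)]
  if (length(obs) == 0L) stop("all MAF values are missing")
  n_missing <- sum(is.na(maf))
  if (n_missing > 0L)
    maf[is.na(maf)] <- sample(obs, n_missing, replace = TRUE)

  edges <- stats::quantile(maf, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE, type = 7)
  edges <- unique(edges)
  if (length(edges) - 1L < n_bins)
    message(sprintf("MAF bins with identical edges merged: %d bins used",
                    length(edges) - 1L))
  bin <- findInterval(maf, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n_bins_eff <- length(edges) - 1L

  full_counts <- tabulate(bin, nbins = n_bins_eff)
  sub_counts <- tabulate(bin[table$indep], nbins = n_bins_eff)
  full_prop <- full_counts / sum(full_counts)

  active <- full_prop > 0 & sub_counts > 0
  if (!any(active)) stop("independent subset and full table share no MAF bin")
  scale <- min(sub_counts[active] / full_prop[active])
  target <- pmin(sub_counts, floor(scale * full_prop))

  keep <- logical(nrow(table))
  idx_indep <- which(table$indep)
  for (b in which(target > 0L)) {
    in_bin <- idx_indep[bin[idx_indep] == b]
    keep[if (length(in_bin) <= target[b]) in_bin else
      sample(in_bin, target[b])] <- TRUE
  }
  keep
}

#' Benjamini-Hochberg adjusted values
#'
#' Standard BH step-up adjustment (a thin validated wrapper around
#' `p.adjust(method = "BH")`), used to turn v-values into FDR values.
#'
#' @param values Numeric vector of probabilities in (0, 1].
#' @return Vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(values) {
  check_p(values, "input")
  stats::p.adjust(values, method = "BH")
}

#' Pipeline configuration
#'
#' @param iterations Character vector of covariate column names, applied in
#'   order; iteration k > 1 consumes the v-values of iteration k - 1 as its
#'   "principal trait" p-values.
#' @param gridp Left-censoring count threshold (default 50).
#' @param dist_thr Spline-correction distance threshold (default 0.5).
#' @param grid_nx,grid_ny Density grid sizes (default 501).
#' @param maf_match Down-sample the independent subset to match the full
#'   table's MAF distribution when a MAF column is available (default TRUE).
#' @param maf_bins Number of equal-probability MAF bins (default 50).
#' @param bh_level Nominal FDR level recorded with the run (default 0.05).
#' @param seed Optional integer seed (MAF imputation/down-sampling).
#' @return A list of class `"flexcfdr_config"`.
#' @export
run_config <- function(iterations, gridp = 50L, dist_thr = 0.5,
                       grid_nx = 501L, grid_ny = 501L, maf_match = TRUE,
                       maf_bins = 50L, bh_level = 0.05, seed = NULL) {
  if (length(iterations) == 0L) stop("at least one covariate iteration must be configured")
  if (gridp < 1L) stop("gridp must be at least 1")
  if (dist_thr <= 0) stop("dist_thr must be positive")
  if (grid_nx < 50L || grid_ny < 50L) stop("grid sizes must be at least 50")
  if (bh_level <= 0 || bh_level >= 1) stop("bh_level must be in (0, 1)")
  structure(list(iterations = iterations, gridp = as.integer(gridp),
                 dist_thr = dist_thr, grid_nx = as.integer(grid_nx),
                 grid_ny = as.integer(grid_ny), maf_match = isTRUE(maf_match),
                 maf_bins = as.integer(maf_bins), bh_level = bh_level,
                 seed = seed),
            class = "flexcfdr_config")
}

#' Run the iterative Flexible cFDR pipeline on a summary table
#'
#' Iteration 1 consumes the raw p-values; iteration k > 1 consumes the
#' v-values of iteration k - 1. Each iteration applies sign alignment,
#' left-censoring, the reflected KDE (fitted on the MAF-matched independent
#' subset), the local fdr fit, the cFDR surface and the L-region mapping to
#' v-values with spline correction. A warning is emitted when two successive
#' covariate columns are strongly correlated (|Pearson r| > 0.3): repeatedly
#' iterating over covariates capturing the same genomic feature erodes FDR
#' control.
#'
#' @param table Summary table from [read_summary_table()] (or an equivalent
#'   data.frame).
#' @param config A `"flexcfdr_config"` from [run_config()].
#' @return The input table with, per iteration k, appended columns
#'   `v_iter<k>`, `fdr_iter<k>` (BH-adjusted), `q_iter<k>_used` and
#'   `corrected_iter<k>`; row order is preserved. Attribute `"flipped"`
#'   records per-iteration sign flips.
#' @export
run_pipeline <- function(table, config) {
  stopifnot(inherits(config, "flexcfdr_config"))
  missing_q <- setdiff(config$iterations, names(table))
  if (length(missing_q) > 0L)
    stop(sprintf("covariate column(s) not in table: %s",
                 paste(missing_q, collapse = ", ")))

  indep <- if (!is.null(table$indep)) table$indep else rep(TRUE, nrow(table))
  fit_mask <- indep
  if (config$maf_match && !is.null(table$maf)) {
    fit_mask <- maf_match_independent_subset(table, n_bins = config$maf_bins,
                                             seed = config$seed)
    message(sprintf("MAF matching retained %d of %d independent SNPs",
                    sum(fit_mask), sum(indep)))
  }

  out <- table
  pcur <- table$p
  prev_q <- NULL
  flips <- logical(length(config$iterations))
  for (k in seq_along(config$iterations)) {
    qk <- table[[config$iterations[k]]]
    if (!is.null(prev_q) && abs(stats::cor(qk, prev_q)) > 0.3)
      warning(sprintf(paste0("covariates '%s' and '%s' are strongly correlated ",
                             "(|r| > 0.3); iterating over covariates that capture ",
                             "the same feature can erode FDR control"),
                      config$iterations[k - 1L], config$iterations[k]))
    res <- flexible_cfdr(pcur, qk, indep = fit_mask,
                         gridp = config$gridp, dist_thr = config$dist_thr,
                         grid_nx = config$grid_nx, grid_ny = config$grid_ny)
    out[[sprintf("v_iter%d", k)]] <- res$v
    out[[sprintf("fdr_iter%d", k)]] <- bh_adjust(res$v)
    out[[sprintf("q_iter%d_used", k)]] <- res$q_used
    out[[sprintf("corrected_iter%d", k)]] <- res$corrected
    flips[k] <- attr(res, "flipped")
    pcur <- res$v
    prev_q <- qk
  }
  attr(out, "flipped") <- flips
  out
}
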