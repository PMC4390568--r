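#' Configuration for significance assessment of the scan
#'
#' @param q_threshold q-value cutoff below which a SNP is called under
#'   selection (default 0.1, i.e. 10% of called SNPs expected false).
#' @param lambda_storey Tuning constant for the Storey pi0 estimate.
#' @param robust_trim Central quantile band used by the alternative trimmed
#'   maximum-likelihood null fit.
#' @param null_method `"medmad"` (default; median/MAD moment matching,
#'   outlier-insensitive) or `"trimmed_ml"` (maximum likelihood on the
#'   central band).
#' @return A `scan_config` list.
#' @export
scan_config <- function(q_threshold = 0.1, lambda_storey = 0.5,
                        robust_trim = c(0.05, 0.95),
                        null_method = c("medmad", "trimmed_ml")) {
  stopifnot(q_threshold > 0, q_threshold < 1,
            lambda_storey > 0, lambda_storey < 1)
  structure(list(q_threshold = q_threshold, lambda_storey = lambda_storey,
                 robust_trim = robust_trim,
                 null_method = match.arg(null_method)),
            class = "scan_config")
}

#' hapFLK statistic at one SNP
#'
#' Multi-allelic extension of the FLK test to haplotype-cluster
#' frequencies. Root cluster frequencies `p0` are estimated per cluster by
#' the FLK root estimator, then renormalized to the simplex; the null
#' covariance is `F (x) B0` with `B0 = diag(p0) - p0 p0'`, inverted in the
#' Moore-Penrose sense (cluster frequencies are linearly constrained).
#' The statistic is invariant to cluster relabeling.
#'
#' @param P J x K matrix of cluster frequencies (populations x clusters).
#' @param kin A `kinship_matrix` (or plain F matrix).
#' @param p0 Optional root frequency vector (length K).
#' @return Non-negative scalar; 0 when frequencies are identical across
#'   populations (including the degenerate all-mass-on-one-cluster case).
#' @export
hapflk_statistic <- function(P, kin, p0 = NULL) {
  F_mat <- if (inherits(kin, "kinship_matrix")) kin$F else kin
  if (is.null(p0)) {
    p0 <- apply(P, 2, estimate_p0, kin = F_mat)
    p0 <- p0 / sum(p0)
  }
  dev <- sweep(P, 2, p0)
  if (all(abs(dev) < 1e-14)) return(0)
  hap_quad_closed(dev, solve(F_mat), p0)
}

# Quadratic form with the closed-form generalized inverse of
# B0 = diag(p0) - p0 p0': on the sum-zero space (where the deviations
# live, both p and p0 being on the simplex) diag(1/p0) is a g-inverse of
# B0, so no eigendecomposition is needed. Clusters with no mass anywhere
# (p0 ~ 0 forces dev = 0) contribute nothing.
hap_quad_closed <- function(dev, Finv, p0, tol = 1e-12) {
  J <- nrow(dev)
  w <- ifelse(p0 > tol, 1 / p0, 0)
  out <- 0
  for (j in seq_len(J)) {
    for (j2 in seq_len(J)) {
      out <- out + Finv[j, j2] * sum(dev[j, ] * dev[j2, ] * w)
    }
  }
  out
}

#' hapFLK values over all SNPs of one fit
#'
#' @param cf J x K x S cluster-frequency array from [cluster_frequencies()].
#' @param kin A `kinship_matrix`.
#' @return Numeric vector of length S.
#' @export
hapflk_values <- function(cf, kin) {
  F_mat <- if (inherits(kin, "kinship_matrix")) kin$F else kin
  Finv <- solve(F_mat)
  w <- solve(F_mat, rep(1, nrow(F_mat)))
  w <- w / sum(w)
  J <- dim(cf)[1]; K <- dim(cf)[2]; S <- dim(cf)[3]
  # vectorized over SNPs: root frequencies, deviations, and the
  # closed-form g-inverse quadratic form (see hap_quad_closed)
  p0 <- matrix(0, S, K)
  slice <- function(j) t(matrix(cf[j, , ], K, S))
  for (j in seq_len(J)) p0 <- p0 + w[j] * slice(j)
  p0 <- pmax(p0, 0)
  p0 <- p0 / pmax(rowSums(p0), .Machine$double.eps)
  iv <- ifelse(p0 > 1e-12, 1 / p0, 0)
  out <- numeric(S)
  for (j in seq_len(J)) {
    devj <- slice(j) - p0
    for (j2 in seq_len(J)) {
      devj2 <- slice(j2) - p0
      out <- out + Finv[j, j2] * rowSums(devj * devj2 * iv)
    }
  }
  pmax(out, 0)
}

#' Haplotype-based differentiation scan
#'
#' Runs `n_fits` independent EM fits of the haplotype-cluster model on all
#' individuals (F1 included), computes per-fit hapFLK from the
#' founder-line cluster frequencies, and averages the statistic over fits.
#'
#' @param g A [geno_matrix()], MAF-filtered and subsampled for the scan.
#' @param kin A `kinship_matrix` estimated from the founder lines.
#' @param ccfg A [cluster_config()].
#' @return Tibble `chrom`, `pos`, `hapflk` with attributes `per_fit`
#'   (S x n_fits matrix) and `n_fits`.
#' @export
hapflk_scan <- function(g, kin, ccfg = cluster_config()) {
  S <- nrow(g$snps)
  per_fit <- matrix(NA_real_, S, ccfg$n_fits)
  for (i in seq_len(ccfg$n_fits)) {
    fit <- em_fit(g, ccfg, fit_index = i)
    cf <- cluster_frequencies(fit$membership, g$samples$population)
    cf <- cf[kin$labels, , , drop = FALSE]
    per_fit[, i] <- hapflk_values(cf, kin)
  }
  out <- tibble(chrom = g$snps$chrom, pos = g$snps$pos,
                hapflk = rowMeans(per_fit))
  attr(out, "per_fit") <- per_fit
  attr(out, "n_fits") <- ccfg$n_fits
  out
}

# Median absolute deviation (unscaled) of a chi-square with d df, solved
# numerically: s such that F(m + s) - F(m - s) = 1/2, m the median.
chisq_mad <- function(d) {
  m <- qchisq(0.5, d)
  uniroot(function(s) pchisq(m + s, d) - pchisq(pmax(m - s, 0), d) - 0.5,
          interval = c(0, m + 60 * sqrt(2 * max(d, 1)) + 60), tol = 1e-10)$root
}

#' Fit the neutral distribution of the scan statistic
#'
#' Models genome-wide hapFLK as `a * chisq_d` and estimates `(a, d)` by
#' matching the sample median and MAD to their chi-square counterparts.
#' Both moments ignore the extreme tails, so the handful of selected loci
#' (outliers by construction) are automatically down-weighted. The
#' alternative `"trimmed_ml"` method maximizes the likelihood of the
#' central `robust_trim` band.
#'
#' @param values Genome-wide statistic values (>= 1000 recommended).
#' @param cfg A [scan_config()].
#' @return List with `a` and `d`, both positive.
#' @export
fit_null <- function(values, cfg = scan_config()) {
  values <- values[is.finite(values)]
  if (length(values) < 1000) {
    warn("fit_null: fewer than 1000 values; null parameters may be unstable")
  }
  med <- median(values)
  m_abs <- median(abs(values - med))
  if (m_abs <= 0 || med <= 0) abort("fit_null: degenerate distribution (zero MAD)")
  if (cfg$null_method == "medmad") {
    obs_ratio <- med / m_abs
    f <- function(ld) {
      d <- exp(ld)
      qchisq(0.5, d) / chisq_mad(d) - obs_ratio
    }
    lo <- log(0.05); hi <- log(500)
    if (f(lo) * f(hi) > 0) {
      # ratio outside the chi-square family range: take the closer endpoint
      d <- if (abs(f(lo)) < abs(f(hi))) exp(lo) else exp(hi)
    } else {
      d <- exp(uniroot(f, c(lo, hi), tol = 1e-9)$root)
    }
    a <- med / qchisq(0.5, d)
  } else {
    qs <- stats::quantile(values, cfg$robust_trim)
    core <- values[values >= qs[1] & values <= qs[2]]
    nll <- function(par) {
      a <- exp(par[1]); d <- exp(par[2])
      -sum(stats::dchisq(core / a, d, log = TRUE) - log(a))
    }
    opt <- stats::optim(c(log(med / 1), log(1)), nll)
    a <- exp(opt$par[1]); d <- exp(opt$par[2])
  }
  list(a = a, d = d)
}

#' p-values from the fitted neutral distribution
#'
#' @param values Statistic values.
#' @param a,d Scaled chi-square null parameters from [fit_null()].
#' @return Upper-tail p-values.
#' @export
pvalues <- function(values, a, d) {
  pchisq(values / a, d, lower.tail = FALSE)
}

#' Storey q-values
#'
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`, then the step-up
#' minimum `q_(i) = min_(j >= i) pi0 m p_(j) / j`.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda Storey tuning constant (default 0.5).
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, lambda = 0.5) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  m <- sum(ok)
  pi0 <- min(1, sum(p[ok] > lambda) / ((1 - lambda) * m))
  o <- order(p[ok])
  q_sorted <- pi0 * m * p[ok][o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- rep(NA_real_, length(p))
  q[ok][o] <- q_sorted
  list(q = q, pi0 = pi0)
}

#' Attach significance to a scan
#'
#' Fits the neutral scaled chi-square to the genome-wide statistic, then
#' assigns p- and q-values; SNPs with `q` below the threshold are flagged
#' as under selection.
#'
#' @param scan Tibble from [hapflk_scan()] (columns `chrom`, `pos`,
#'   `hapflk`).
#' @param cfg A [scan_config()].
#' @return An object of class `hapflk_scan`: list with `table` (tibble
#'   adding `p`, `q`, `significant`), `null` (`a`, `d`, `pi0`), `config`,
#'   `n_fits`.
#' @export
scan_significance <- function(scan, cfg = scan_config()) {
  null <- fit_null(scan$hapflk, cfg)
  p <- pvalues(scan$hapflk, null$a, null$d)
  qv <- qvalues(p, cfg$lambda_storey)
  tab <- scan |>
    mutate(p = p, q = qv$q, significant = .data$q < cfg$q_threshold)
  structure(list(table = tab,
                 null = list(a = null$a, d = null$d, pi0 = qv$pi0),
                 config = cfg,
                 n_fits = attr(scan, "n_fits") %||% NA_integer_),
            class = "hapflk_scan")
}

#' @export
print.hapflk_scan <- function(x, ...) {
  cat(sprintf("<hapflk_scan> %d SNPs, null ~ %.3g * chisq(%.2f), pi0 = %.3f\n",
              nrow(x$table), x$null$a, x$null$d, x$null$pi0))
  cat(sprintf("  %d SNP(s) with q < %.2g\n",
              sum(x$table$significant, na.rm = TRUE), x$config$q_threshold))
  invisible(x)
}

#' @describeIn scan_significance Per-SNP tibble of the scan.
#' @param x A `hapflk_scan` object.
#' @param ... Unused.
#' @export
tidy.hapflk_scan <- function(x, ...) x$table

#' @describeIn scan_significance One-row model summary (null parameters,
#'   pi0, SNP counts).
#' @export
glance.hapflk_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$table),
         n_significant = sum(x$table$significant, na.rm = TRUE),
         null_a = x$null$a, null_d = x$null$d, pi0 = x$null$pi0,
         n_fits = x$n_fits)
}

#' Genome-scan plot of a hapFLK scan
#'
#' @param object A `hapflk_scan`.
#' @param ... Unused.
#' @return A ggplot: -log10 p along the genome, faceted by chromosome,
#'   significant SNPs highlighted.
#' @export
autoplot.hapflk_scan <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pos / 1e6,
                                    y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)))
}

#' Full sweep-detection pipeline on a genotype matrix
#'
#' MAF filter, kinship on a sparse subsample, haplotype-cluster scan on a
#' denser subsample, neutral-null significance — the complete path from
#' genotypes to a scored scan.
#'
#' @param g A [geno_matrix()] with founder-line and F1 individuals.
#' @param maf_min MAF threshold (default 0.10; "below 10% removed").
#' @param kinship_fraction,scan_fraction SNP subsample fractions (defaults
#'   0.01 and 0.30).
#' @param subsample_seed Seed for both subsamples.
#' @param ccfg A [cluster_config()].
#' @param scfg A [scan_config()].
#' @return A `hapflk_scan` object; the kinship matrix is attached as
#'   attribute `kinship`.
#' @export
run_sweep_scan <- function(g, maf_min = 0.10, kinship_fraction = 0.01,
                           scan_fraction = 0.30, subsample_seed = 1L,
                           ccfg = cluster_config(), scfg = scan_config()) {
  gf <- filter_maf(g, allele_frequencies(g), maf_min = maf_min)
  kin <- estimate_kinship(gf, kinship_fraction, seed = subsample_seed)
  gs <- subsample_snps(gf, scan_fraction, seed = subsample_seed + 1L)
  scan <- hapflk_scan(gs, kin, ccfg)
  res <- scan_significance(scan, scfg)
  attr(res, "kinship") <- kin
  res
}
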