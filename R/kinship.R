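#' Reynolds genetic distance between two populations
#'
#' Coancestry distance computed from per-SNP allele frequencies; under pure
#' drift it grows approximately linearly with divergence time, which is what
#' makes it a suitable branch-length estimate for the drift covariance
#' matrix. For biallelic SNPs with alt frequencies `p_i`, `p_j`:
#' numerator `sum_s (p_i - p_j)^2`, denominator
#' `sum_s (1 - p_i p_j - (1-p_i)(1-p_j))`.
#'
#' @param p_i,p_j Numeric vectors of alt-allele frequencies over the same
#'   SNPs, no missing values.
#' @return Distance in `[0, 1]`.
#' @export
reynolds_distance <- function(p_i, p_j) {
  stopifnot(length(p_i) == length(p_j), !anyNA(p_i), !anyNA(p_j))
  num <- sum(0.5 * ((p_i - p_j)^2 + ((1 - p_i) - (1 - p_j))^2))
  den <- sum(1 - p_i * p_j - (1 - p_i) * (1 - p_j))
  if (den == 0) {
    abort("Reynolds distance undefined: all SNPs identically fixed in both populations")
  }
  num / den
}

#' Pairwise Reynolds distance matrix
#'
#' @param freq Frequency tibble from [allele_frequencies()] (uses the
#'   `freq_*` columns); rows with any missing frequency are dropped.
#' @return Symmetric labelled matrix of pairwise distances.
#' @export
reynolds_matrix <- function(freq) {
  fcols <- grep("^freq_", names(freq), value = TRUE)
  labels <- sub("^freq_", "", fcols)
  fm <- as.matrix(freq[fcols])
  fm <- fm[complete.cases(fm), , drop = FALSE]
  J <- length(labels)
  D <- matrix(0, J, J, dimnames = list(labels, labels))
  for (i in seq_len(J)) {
    for (j in seq_len(J)) {
      if (i < j) D[i, j] <- D[j, i] <- reynolds_distance(fm[, i], fm[, j])
    }
  }
  D
}

#' Drift kinship matrix from Reynolds distances
#'
#' Builds the expected drift covariance matrix F among populations. With two
#' populations the (unrooted) tree is a single edge, rooted at its midpoint:
#' `F = diag(D/2, D/2)`. With more populations a neighbor-joining tree is
#' fitted, midpoint-rooted, and `F[j,j]` is the root-to-leaf branch sum while
#' `F[j,k]` is the shared branch length of leaves j and k.
#'
#' @param reynolds Symmetric non-negative distance matrix with labelled rows.
#' @param branch_split With two populations, the fraction of the distance
#'   assigned to the first population's branch (default 0.5, midpoint
#'   rooting; there is no outgroup in a two-line design so the symmetric
#'   split is the natural choice).
#' @return Object of class `kinship_matrix`: list with `F`, `reynolds`,
#'   `labels`.
#' @export
kinship_from_distances <- function(reynolds, branch_split = 0.5) {
  stopifnot(is.matrix(reynolds), nrow(reynolds) == ncol(reynolds),
            isTRUE(all.equal(reynolds, t(reynolds), tolerance = 1e-8)))
  labels <- rownames(reynolds) %||% paste0("pop", seq_len(nrow(reynolds)))
  J <- nrow(reynolds)
  if (J == 2) {
    d <- reynolds[1, 2]
    F_mat <- diag(c(branch_split * d, (1 - branch_split) * d))
  } else {
    tree <- ape::nj(stats::as.dist(reynolds))
    if (any(tree$edge.length < 0)) {
      warn("negative neighbor-joining branch lengths clamped to 0")
      tree$edge.length <- pmax(tree$edge.length, 0)
    }
    tree <- phangorn::midpoint(tree)
    F_mat <- shared_branch_matrix(tree, labels)
  }
  dimnames(F_mat) <- list(labels, labels)
  structure(list(F = F_mat, reynolds = reynolds, labels = labels),
            class = "kinship_matrix")
}

# Shared root-to-leaf branch lengths on a rooted tree: F[j,k] is the length
# of the path from the root to the most recent common ancestor of j and k.
shared_branch_matrix <- function(tree, labels) {
  root <- length(tree$tip.label) + 1L
  dn <- ape::dist.nodes(tree)
  J <- length(labels)
  F_mat <- matrix(0, J, J)
  tips <- match(labels, tree$tip.label)
  for (j in seq_len(J)) {
    for (k in j:J) {
      mrca <- if (j == k) tips[j] else ape::getMRCA(tree, c(tips[j], tips[k]))
      F_mat[j, k] <- F_mat[k, j] <- dn[root, mrca]
    }
  }
  F_mat
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix>", length(x$labels), "populations\n")
  print(round(x$F, 5))
  invisible(x)
}

#' Export a kinship matrix (and Reynolds distances) as TSV
#'
#' @param kin A [kinship_from_distances()] result.
#' @param path Output TSV path for F; Reynolds distances are written next to
#'   it with suffix `_reynolds.tsv`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path) {
  write.table(kin$F, path, sep = "\t", quote = FALSE, col.names = NA)
  write.table(kin$reynolds, sub("\\.tsv$", "_reynolds.tsv", path),
              sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Estimate kinship from a genotype matrix
#'
#' Convenience wrapper: allele frequencies of the founder-line individuals
#' on a sparse SNP subsample (kinship needs few SNPs), Reynolds distances,
#' then [kinship_from_distances()].
#'
#' @param g A MAF-filtered [geno_matrix()].
#' @param kinship_fraction Fraction of SNPs used (default 0.01).
#' @param seed Subsampling seed.
#' @param branch_split See [kinship_from_distances()].
#' @return A `kinship_matrix`.
#' @export
estimate_kinship <- function(g, kinship_fraction = 0.01, seed = 1L,
                             branch_split = 0.5) {
  gk <- subsample_snps(g, kinship_fraction, seed = seed)
  D <- reynolds_matrix(allele_frequencies(gk))
  kinship_from_distances(D, branch_split = branch_split)
}

#' Ancestral allele frequency under the drift model
#'
#' Generalized-least-squares estimate of the root frequency:
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`, clipped to `[0, 1]`. Falls back to the
#' unweighted mean with a warning when F is singular.
#'
#' @param p Per-population frequencies at one SNP (vector of length J), or a
#'   matrix with J columns for vectorized evaluation over SNPs in rows.
#' @param kin A `kinship_matrix` (or a plain F matrix).
#' @return Estimated root frequency (vector when `p` is a matrix).
#' @export
estimate_p0 <- function(p, kin) {
  F_mat <- if (inherits(kin, "kinship_matrix")) kin$F else kin
  w <- tryCatch(solve(F_mat, rep(1, nrow(F_mat))),
                error = function(e) NULL)
  if (is.null(w)) {
    warn("singular kinship matrix: using unweighted mean for p0")
    w <- rep(1, nrow(F_mat))
  }
  w <- w / sum(w)
  if (is.matrix(p)) {
    pmin(pmax(drop(p %*% w), 0), 1)
  } else {
    min(max(sum(w * p), 0), 1)
  }
}

#' Single-SNP FLK statistic
#'
#' Tests whether allele-frequency differences among populations exceed what
#' drift (as encoded by the kinship matrix) can explain:
#' `T = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1)`.
#'
#' @param p Per-population alt frequencies at one SNP (length J).
#' @param kin A `kinship_matrix` or plain F matrix.
#' @param p0 Optional root frequency; estimated by [estimate_p0()] if `NULL`.
#' @return Non-negative statistic; `NA` when the estimated root frequency is
#'   0 or 1 (non-informative SNP).
#' @export
flk_statistic <- function(p, kin, p0 = NULL) {
  F_mat <- if (inherits(kin, "kinship_matrix")) kin$F else kin
  if (is.null(p0)) p0 <- estimate_p0(p, F_mat)
  if (p0 <= 0 || p0 >= 1) return(NA_real_)
  dev <- p - p0
  drop(crossprod(dev, solve(p0 * (1 - p0) * F_mat, dev)))
}

#' FLK scan over a frequency table
#'
#' @param freq Output of [allele_frequencies()].
#' @param kin A `kinship_matrix`.
#' @return Tibble `chrom`, `pos`, `flk` (`NA` for non-informative SNPs,
#'   whose count is reported via a message).
#' @export
flk_scan <- function(freq, kin) {
  fcols <- paste0("freq_", kin$labels)
  stopifnot(all(fcols %in% names(freq)))
  pm <- as.matrix(freq[fcols])
  p0 <- estimate_p0(pm, kin)
  Finv <- solve(kin$F)
  dev <- pm - p0
  quad <- rowSums((dev %*% Finv) * dev)
  v <- quad / (p0 * (1 - p0))
  v[p0 <= 0 | p0 >= 1 | !complete.cases(pm)] <- NA_real_
  n_bad <- sum(is.na(v))
  if (n_bad > 0) {
    inform(sprintf("flk_scan: %d non-informative SNP(s) excluded", n_bad))
  }
  tibble(chrom = freq$chrom, pos = freq$pos, flk = v)
}
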