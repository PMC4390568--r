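#' Configuration for the haplotype-cluster model
#'
#' The latent clusters play the role of ancestral haplotypes; in the
#' divergent-line design the default `K = 6` matches the six ancestral
#' lines mixed in the founder stock. Several independent EM fits are run
#' from random starts and the scan statistic is averaged over fits (the
#' statistic is invariant to cluster labels, so no label alignment is
#' needed).
#'
#' @param K Number of haplotype clusters (default 6).
#' @param n_fits Independent EM fits averaged downstream (default 10).
#' @param em_iterations Baum-Welch iterations per fit (default 25).
#' @param seed Base seed; fit `i` uses a stream derived from `(seed, i)`.
#' @param convergence_tol Relative log-likelihood change for early stopping.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(K = 6L, n_fits = 10L, em_iterations = 25L,
                           seed = 1L, convergence_tol = 1e-6) {
  stopifnot(K >= 1, n_fits >= 1, em_iterations >= 1)
  structure(list(K = as.integer(K), n_fits = as.integer(n_fits),
                 em_iterations = as.integer(em_iterations),
                 seed = as.integer(seed), convergence_tol = convergence_tol),
            class = "cluster_config")
}

# Emission floor keeping theta away from {0,1}; degenerate emissions make
# the forward pass collapse.
THETA_FLOOR <- 1e-3

#' Initialize haplotype-cluster model parameters
#'
#' Cluster weights start uniform; emission probabilities are drawn uniform
#' in `[0.05, 0.95]` from a stream seeded by `(seed, fit_index)` so fits are
#' reproducible and distinct. The jump probability between adjacent SNPs is
#' initialized from physical distance `d` as `r = 1 - exp(-d / 50000)`
#' (about one expected cluster switch per 50 kb); chromosome boundaries get
#' `r = 1` (complete redraw, no linkage across chromosomes).
#'
#' @param cfg A [cluster_config()].
#' @param snps Tibble with `chrom` and `pos` for the SNPs to be modelled.
#' @param fit_index Which independent fit this initialization seeds.
#' @return A `cluster_model` list with `theta` (S x K), `alpha` (S x K),
#'   `r` (length S, first entry 0) and `loglik = NA`.
#' @export
init_params <- function(cfg, snps, fit_index = 1L) {
  S <- nrow(snps)
  K <- cfg$K
  theta <- with_rng(cfg$seed + 1009L * as.integer(fit_index),
                    matrix(runif(S * K, 0.05, 0.95), S, K))
  alpha <- matrix(1 / K, S, K)
  d <- c(0, diff(snps$pos))
  new_chrom <- c(FALSE, snps$chrom[-1] != snps$chrom[-S])
  r <- 1 - exp(-pmax(d, 0) / 50000)
  r[new_chrom] <- 1 - 1e-12
  r[1] <- 0
  structure(list(theta = theta, alpha = alpha, r = r, loglik = NA_real_),
            class = "cluster_model")
}

#' Forward-backward over unordered cluster pairs for one individual
#'
#' Computes the posterior over the `K(K+1)/2` unordered cluster pairs at
#' each SNP, and the genotype log-likelihood, marginalizing missing
#' genotypes. Phase is never needed: the two chromosomes are treated as
#' exchangeable.
#'
#' @param dosages Integer vector of alt dosages (0/1/2, `NA` missing).
#' @param model A `cluster_model`.
#' @return List with `pair_posterior` (S x K(K+1)/2 matrix, columns ordered
#'   (1,1),(1,2),...,(1,K),(2,2),...) and `loglik`.
#' @export
genotype_forward_backward <- function(dosages, model) {
  stopifnot(length(dosages) == nrow(model$theta))
  res <- hmm_forward_backward_cpp(as.integer(dosages), model$theta,
                                  model$alpha, model$r)
  K <- ncol(model$theta)
  pairs <- which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(res$pair_posterior) <- paste0(pairs[, 1], "-", pairs[, 2])
  res
}

#' Fit the haplotype-cluster model by EM
#'
#' Baum-Welch on the unphased-genotype HMM for all individuals, crossbred
#' F1 included (they carry one chromosome from each line, so they enlarge
#' the sample for haplotype inference without entering line frequencies).
#' All M-step updates use exact expected sufficient statistics, so the
#' training log-likelihood is non-decreasing.
#'
#' @param g A [geno_matrix()] (MAF-filtered, typically subsampled).
#' @param cfg A [cluster_config()].
#' @param fit_index Index of this fit (seeds the initialization).
#' @return List with `model` (a `cluster_model` with final `loglik` and the
#'   iteration trace in `loglik_trace`) and `membership`, a K x S x N array
#'   of expected chromosome counts per cluster (each column sums to 2).
#' @export
em_fit <- function(g, cfg, fit_index = 1L) {
  if (nrow(g$samples) < 2) abort("em_fit needs at least 2 individuals")
  if (nrow(g$snps) < 1) abort("em_fit: empty genotype matrix")
  init <- init_params(cfg, g$snps, fit_index)
  res <- hmm_em_cpp(g$dosage, init$theta, init$alpha, init$r,
                    cfg$em_iterations, cfg$convergence_tol, THETA_FLOOR)
  model <- structure(
    list(theta = res$theta, alpha = res$alpha, r = res$r,
         loglik = tail(res$loglik_trace, 1),
         loglik_trace = res$loglik_trace),
    class = "cluster_model")
  N <- nrow(g$samples)
  S <- nrow(g$snps)
  membership <- array(t(res$membership), dim = c(cfg$K, S, N),
                      dimnames = list(NULL, NULL, g$samples$id))
  list(model = model, membership = membership)
}

#' Per-population haplotype-cluster frequencies
#'
#' Averages posterior cluster memberships over the individuals of each
#' founder-line population (F1 individuals are excluded: their cluster
#' content mixes both lines). Each frequency vector lies on the K-simplex.
#'
#' @param membership K x S x N array from [em_fit()].
#' @param populations Population label per individual (length N, third
#'   dimension order).
#' @param f1_label Label excluded from frequencies (default `"F1"`).
#' @return J x K x S array of cluster frequencies, populations in rows.
#' @export
cluster_frequencies <- function(membership, populations, f1_label = "F1") {
  stopifnot(dim(membership)[3] == length(populations))
  pops <- setdiff(unique(populations), f1_label)
  K <- dim(membership)[1]
  S <- dim(membership)[2]
  out <- array(NA_real_, dim = c(length(pops), K, S),
               dimnames = list(pops, NULL, NULL))
  for (j in seq_along(pops)) {
    idx <- which(populations == pops[j])
    m <- membership[, , idx, drop = FALSE]
    out[j, , ] <- apply(m, c(1, 2), sum) / (2 * length(idx))
  }
  out
}
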