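#' Relative expression from cycle thresholds
#'
#' One qPCR cycle corresponds to a two-fold difference, so expression
#' relative to a reference gene is `2^-(Ct_target - Ct_reference)`.
#'
#' @param ct_target,ct_reference Numeric Ct vectors (paired).
#' @return Relative expression values; samples with a missing Ct yield `NA`
#'   with a message.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(length(ct_target) == length(ct_reference))
  miss <- is.na(ct_target) | is.na(ct_reference)
  if (any(miss)) {
    inform(sprintf("relative_expression: %d sample(s) with missing Ct excluded",
                   sum(miss)))
  }
  out <- 2^(-(ct_target - ct_reference))
  out[miss] <- NA_real_
  out
}

#' Differential expression between two groups
#'
#' Unpaired two-tailed Student t-test on relative expression values
#' (2^-dCt scale); the fold change is the ratio of group means.
#'
#' @param expr_a,expr_b Relative expression values for the two groups
#'   (at least 2 non-missing each).
#' @param var_equal Use the pooled-variance Student test (default `TRUE`).
#' @return One-row tibble: `fold_change` (A over B), `t`, `df`, `p`,
#'   `n_a`, `n_b`. Two degenerate equal-constant groups give `p = 1`.
#' @export
differential_expression <- function(expr_a, expr_b, var_equal = TRUE) {
  expr_a <- expr_a[!is.na(expr_a)]
  expr_b <- expr_b[!is.na(expr_b)]
  stopifnot(length(expr_a) >= 2, length(expr_b) >= 2)
  fold <- mean(expr_a) / mean(expr_b)
  if (sd(expr_a) == 0 && sd(expr_b) == 0) {
    if (mean(expr_a) == mean(expr_b)) {
      return(tibble(fold_change = 1, t = 0,
                    df = length(expr_a) + length(expr_b) - 2, p = 1,
                    n_a = length(expr_a), n_b = length(expr_b)))
    }
    return(tibble(fold_change = fold, t = Inf,
                  df = length(expr_a) + length(expr_b) - 2, p = 0,
                  n_a = length(expr_a), n_b = length(expr_b)))
  }
  tt <- t.test(expr_a, expr_b, var.equal = var_equal)
  tibble(fold_change = fold, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         n_a = length(expr_a), n_b = length(expr_b))
}

#' Tissue expression profile as fold changes
#'
#' Samples with target Ct above `ct_max` are excluded (the gene is treated
#' as not expressed there); among retained tissues, the one with the
#' highest mean Ct (lowest expression) is the reference, and each tissue's
#' fold change is `2^(Ct_ref - Ct_tissue) >= 1`.
#'
#' @param ct_by_tissue Tibble with columns `tissue` and `ct` (one row per
#'   sample; replicate rows per tissue are averaged).
#' @param ct_max Exclusion threshold (default 30).
#' @return Tibble `tissue`, `mean_ct`, `n`, `fold_change`, sorted by
#'   decreasing fold change; empty (with a warning) when no tissue is
#'   retained.
#' @export
tissue_profile <- function(ct_by_tissue, ct_max = 30) {
  kept <- filter(ct_by_tissue, !is.na(.data$ct), .data$ct <= ct_max)
  if (nrow(kept) == 0) {
    warn("tissue_profile: no tissue with Ct at or below the threshold")
    return(tibble(tissue = character(), mean_ct = numeric(), n = integer(),
                  fold_change = numeric()))
  }
  prof <- kept |>
    group_by(.data$tissue) |>
    summarise(mean_ct = mean(.data$ct), n = n(), .groups = "drop")
  ref <- max(prof$mean_ct)
  prof |>
    mutate(fold_change = 2^(ref - .data$mean_ct)) |>
    arrange(dplyr::desc(.data$fold_change))
}

#' gDNA-standardized allelic ratio
#'
#' Ratio of reference-to-alternative allele odds in cDNA over the same
#' odds in gDNA. The gDNA of a heterozygote is balanced in truth, so
#' dividing by its measured odds cancels any assay skew; a ratio of 1
#' means equal expression of the two alleles.
#'
#' @param gdna_ref,cdna_ref Reference-allele frequencies in gDNA and cDNA
#'   (each strictly inside (0, 1)).
#' @return Allelic ratio (vectorized).
#' @export
allelic_ratio <- function(gdna_ref, cdna_ref) {
  if (any(gdna_ref <= 0 | gdna_ref >= 1 | cdna_ref <= 0 | cdna_ref >= 1)) {
    abort("allelic_ratio undefined: frequencies must be strictly inside (0, 1)")
  }
  (cdna_ref / (1 - cdna_ref)) / (gdna_ref / (1 - gdna_ref))
}

# Exact null distribution of the Wilcoxon signed-rank sum of positives,
# with midranks for ties: generating-function dynamic programme over the
# 2^n equiprobable sign assignments. Ranks are doubled so midranks are
# integers. Returns P(V <= v) and P(V >= v).
signed_rank_exact <- function(v_obs2, ranks2) {
  total <- sum(ranks2)
  dist <- numeric(total + 1)
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  le <- sum(dist[seq_len(v_obs2 + 1)])
  ge <- sum(dist[(v_obs2 + 1):(total + 1)])
  c(le = le, ge = ge)
}

#' Test of allelic imbalance against a balanced ratio of 1
#'
#' One-sample Wilcoxon signed-rank test of `log(ratio)` against 0. The
#' exact two-tailed p-value is computed for `n <= 25` by enumerating the
#' sign-flip distribution (midranks handle ties, so a set of identical
#' ratios still gets its exact `2/2^n`); larger samples use the normal
#' approximation with tie correction.
#'
#' @param ratios Allelic ratios from [allelic_ratio()] (>= 3 values).
#' @return One-row tibble: `n`, `mean_ratio`, `statistic` (rank sum of
#'   ratios above 1), `p`.
#' @export
ase_test <- function(ratios) {
  stopifnot(length(ratios) >= 3, all(ratios > 0))
  lr <- log(ratios)
  nz <- lr[lr != 0]
  n <- length(nz)
  if (n == 0) {
    return(tibble(n = length(ratios), mean_ratio = mean(ratios),
                  statistic = 0, p = 1))
  }
  ranks <- rank(abs(nz))
  v <- sum(ranks[nz > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * ranks))
    pr <- signed_rank_exact(as.integer(round(2 * v)), ranks2)
    p <- min(1, 2 * min(pr))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- min(1, 2 * pnorm(-abs(v - mu) / sqrt(sig2)))
  }
  tibble(n = length(ratios), mean_ratio = mean(ratios), statistic = v, p = p)
}

#' Allele-specific expression analysis of a pyrosequencing table
#'
#' Averages technical duplicates within individual, drops homozygous
#' individuals (gDNA frequency at 0 or 1 carries no allelic signal), forms
#' gDNA-standardized allelic ratios and tests them against balance.
#'
#' @param ase_tbl Tibble with columns `individual`, `gdna_ref`, `cdna_ref`
#'   and optionally `replicate`.
#' @param pool_replicates Treat each replicate as an observation instead of
#'   averaging within individual (default `FALSE`).
#' @return List with `ratios` (per-individual tibble) and `test` (the
#'   [ase_test()] row).
#' @export
ase_analysis <- function(ase_tbl, pool_replicates = FALSE) {
  het <- filter(ase_tbl, .data$gdna_ref > 0, .data$gdna_ref < 1,
                .data$cdna_ref > 0, .data$cdna_ref < 1)
  n_hom <- length(setdiff(unique(ase_tbl$individual), unique(het$individual)))
  if (n_hom > 0) {
    inform(sprintf("ase_analysis: %d homozygous individual(s) removed", n_hom))
  }
  if (!pool_replicates) {
    het <- het |>
      group_by(.data$individual) |>
      summarise(gdna_ref = mean(.data$gdna_ref),
                cdna_ref = mean(.data$cdna_ref), .groups = "drop")
  }
  het <- mutate(het, ratio = allelic_ratio(.data$gdna_ref, .data$cdna_ref))
  list(ratios = het, test = ase_test(het$ratio))
}

#' Correlation between expression and a phenotype
#'
#' Pearson product-moment correlation with the two-tailed t-based p-value.
#'
#' @param expr,pheno Paired numeric vectors (n >= 3).
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
expression_phenotype_correlation <- function(expr, pheno) {
  ok <- !is.na(expr) & !is.na(pheno)
  expr <- expr[ok]; pheno <- pheno[ok]
  stopifnot(length(expr) >= 3)
  if (sd(expr) == 0 || sd(pheno) == 0) {
    abort("correlation undefined: zero variance")
  }
  ct <- cor.test(expr, pheno)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(expr))
}
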