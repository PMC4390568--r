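# Shared fixture builders and independent oracles.

# Minimal VCF writer for test inputs (plain text, GT only).
write_test_vcf <- function(path, chrom, pos, ref, alt, gt_rows, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", ".", ".", "GT",
            gt_rows[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Small genotype container straight from a dosage matrix.
toy_geno <- function(dosage, populations, chrom = "chr1",
                     pos = seq(1000, by = 1000, length.out = ncol(dosage))) {
  geno_matrix(
    snps = tibble::tibble(chrom = chrom, pos = pos,
                          ref = rep("A", ncol(dosage)),
                          alt = rep("C", ncol(dosage))),
    samples = tibble::tibble(id = paste0("s", seq_len(nrow(dosage))),
                             population = populations),
    dosage = dosage)
}

# Brute-force oracle for the pair HMM: enumerate every ordered pair of
# cluster paths and sum their joint probabilities.
brute_force_pair_posterior <- function(dosages, model) {
  S <- length(dosages)
  K <- ncol(model$theta)
  emit <- function(g, tk, tl) {
    if (is.na(g)) return(1)
    if (g == 0) (1 - tk) * (1 - tl)
    else if (g == 1) tk * (1 - tl) + (1 - tk) * tl
    else tk * tl
  }
  path_prob <- function(path) {
    p <- model$alpha[1, path[1]]
    if (S > 1) {
      for (s in 2:S) {
        r <- model$r[s]
        p <- p * ((1 - r) * (path[s] == path[s - 1]) + r * model$alpha[s, path[s]])
      }
    }
    p
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), S)))
  post <- array(0, c(S, K, K))
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    for (j in seq_len(nrow(paths))) {
      w <- path_prob(paths[i, ]) * path_prob(paths[j, ])
      for (s in seq_len(S)) {
        w <- w * emit(dosages[s], model$theta[s, paths[i, s]],
                      model$theta[s, paths[j, s]])
      }
      tot <- tot + w
      for (s in seq_len(S)) {
        post[s, paths[i, s], paths[j, s]] <-
          post[s, paths[i, s], paths[j, s]] + w
      }
    }
  }
  post <- post / tot
  tot <- unname(tot)
  # collapse ordered pairs to unordered (k <= l)
  un <- matrix(0, S, K * (K + 1) / 2)
  idx <- 1
  for (k in seq_len(K)) {
    for (l in k:K) {
      un[, idx] <- if (l == k) post[, k, k] else post[, k, l] + post[, l, k]
      idx <- idx + 1
    }
  }
  list(pair_posterior = un, loglik = log(tot))
}

# Independent hapFLK oracle: full Kronecker covariance and an
# eigendecomposition-based pseudo-inverse, nothing shared with the
# implementation's fast path.
hapflk_oracle <- function(P, F_mat) {
  J <- nrow(P); K <- ncol(P)
  w <- solve(F_mat, rep(1, J)); w <- w / sum(w)
  p0 <- as.numeric(w %*% P)
  p0 <- pmin(pmax(p0, 0), 1)
  p0 <- p0 / sum(p0)
  B0 <- diag(p0) - outer(p0, p0)
  V <- kronecker(F_mat, B0)
  e <- eigen(V, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  Vp <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*% t(e$vectors[, keep, drop = FALSE])
  dev <- as.numeric(t(P - matrix(p0, J, K, byrow = TRUE)))  # j-major, k inner
  drop(t(dev) %*% Vp %*% dev)
}

# Random simplex vectors for property tests.
rsimplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# A two-gene toy annotation setting shared by consequence tests:
# gene A on + strand, gene B on - strand, explicit sequence.
toy_annotation <- function() {
  # chromosome of 300 bp
  seqs <- paste(rep("ACGT", 100), collapse = "")
  genome <- list(chrT = seqs)
  # gene A (+): exon1 21..50 (CDS 31..50), intron 51..80, exon2 81..130
  # (CDS 81..116, UTR 117..130); CDS length 20 + 36 = 56 -> not /3!
  # use CDS 31..50 (20) + 81..120 (40) = 60, exon2 81..134
  tx <- tibble::tibble(
    transcript_id = c("tA.1", "tA.1", "tA.1", "tA.1"),
    gene_id = "geneA",
    chrom = "chrT",
    strand = "+",
    type = c("exon", "CDS", "exon", "CDS"),
    start = c(21, 31, 81, 81),
    end = c(50, 50, 134, 120))
  # gene B (-): single exon 201..260, CDS 211..252 (42 bp)
  txB <- tibble::tibble(
    transcript_id = "tB.1", gene_id = "geneB", chrom = "chrT", strand = "-",
    type = c("exon", "CDS"), start = c(201, 211), end = c(260, 252))
  list(genome = genome, transcripts = rbind(tx, txB))
}
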