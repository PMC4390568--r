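small_params <- function(...) {
  design_params(chrom_lengths = c(8e5, 6e5), seed = 77, ...)
}

test_that("founder pools are reproducible with Poisson-consistent SNP counts", {
  p <- small_params()
  f1 <- make_founders(p)
  f2 <- make_founders(p)
  expect_identical(f1$haps, f2$haps)
  expect_identical(f1$snps, f2$snps)
  # SNP count ~ Poisson(density * length)
  lambda <- p$snp_density * sum(p$chrom_lengths) / 1000
  expect_lt(abs(nrow(f1$snps) - lambda), 5 * sqrt(lambda))
  # 23 + 68 founders, two haplotypes each
  expect_equal(ncol(f1$haps[[1]]), 2 * (23 + 68))
  expect_equal(f1$sex, rep(c("M", "F"), c(23, 68)))
})

test_that("a single ancestral line leaves no between-group structure", {
  p <- design_params(chrom_lengths = 4e5, n_ancestral_lines = 1, seed = 3)
  fo <- make_founders(p)
  H <- fo$haps[[1]]
  freq_a <- rowMeans(H[, 1:90])
  freq_b <- rowMeans(H[, 91:182])
  D <- reynolds_distance(freq_a, freq_b)
  expect_lt(D, 0.02)
})

test_that("ancestral-line structure is worth six clusters on held-out founders", {
  p <- design_params(chrom_lengths = 1e5, seed = 9)
  fo <- make_founders(p)
  H <- fo$haps[[1]]
  S <- nrow(H)
  dos <- t(H[, seq(1, ncol(H) - 1, by = 2)] + H[, seq(2, ncol(H), by = 2)])
  # founders are assigned to lines round-robin, so consecutive blocks
  # cover every ancestral line in both halves
  train <- 1:46; test <- 47:91
  g_train <- toy_geno(dos[train, ], populations = rep("lineA", length(train)),
                      pos = fo$snps$pos)
  heldout_ll <- function(K) {
    fit <- em_fit(g_train, cluster_config(K = K, em_iterations = 25, seed = 4))
    sum(vapply(test, function(i) {
      genotype_forward_backward(dos[i, ], fit$model)$loglik
    }, numeric(1)))
  }
  expect_gt(heldout_ll(6), heldout_ll(1))
})

test_that("meioses respect Mendelian inheritance and the crossover process", {
  set.seed(80)
  S <- 500
  pos <- sort(sample.int(1e6, S))
  h1 <- rbinom(S, 1, 0.5); h2 <- rbinom(S, 1, 0.5)
  # rate 0: the gamete is one parental haplotype verbatim
  g0 <- meiosis_gamete(h1, h2, pos, 0)
  expect_true(identical(as.integer(g0), h1) || identical(as.integer(g0), h2))
  expect_equal(attr(g0, "crossovers"), 0)
  # any rate: every allele traces to a parental haplotype at that SNP
  for (i in 1:20) {
    g <- meiosis_gamete(h1, h2, pos, 5e-6)
    expect_true(all(g == h1 | g == h2))
  }
  # crossover counts are Poisson with the right mean
  nc <- replicate(400, attr(meiosis_gamete(h1, h2, pos, 2e-6), "crossovers"))
  lambda <- 2e-6 * (max(pos) - min(pos))
  expect_lt(abs(mean(nc) - lambda), 4 * sqrt(lambda / 400))
})

test_that("the simulated design is reproducible and correctly shaped", {
  p <- small_params()
  s1 <- simulate_design(p)
  s2 <- simulate_design(p)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  g <- s1$genotypes
  expect_equal(table(g$samples$population)[c("lineA", "lineB", "F1")],
               table(factor(rep(c("lineA", "lineB", "F1"), c(7, 4, 9)),
                            levels = c("lineA", "lineB", "F1")))[c("lineA", "lineB", "F1")])
  expect_true(all(g$dosage %in% 0:2))
  by_chrom <- split(g$snps$pos, g$snps$chrom)
  expect_true(all(vapply(by_chrom, function(x) all(diff(x) > 0), logical(1))))
  expect_equal(nrow(s1$truth$line_means), 2 * 35)
})

test_that("truncation selection drives divergence and sweeps the QTN", {
  p <- small_params()
  sim <- simulate_design(p)
  lm <- sim$truth$line_means
  sel_end <- lm[lm$generation == p$selection_generations, ]
  expect_gt(sel_end$mean_genetic[sel_end$line == "lineB"],
            sel_end$mean_genetic[sel_end$line == "lineA"])
  # divergence grows in expectation over the selection phase
  d_first <- diff(rev(lm$mean_genetic[lm$generation == 1]))
  d_last <- diff(rev(lm$mean_genetic[lm$generation == p$selection_generations]))
  expect_gt(abs(d_last), abs(d_first))
  # the favourable allele rises in line B, is lost in line A, and ends more
  # differentiated than almost every neutral SNP
  expect_gt(sim$truth$qtn$freq_lineB - sim$truth$qtn$freq_lineA, 0.5)
  fr <- allele_frequencies(sim$genotypes)
  dd <- abs(fr$freq_lineA - fr$freq_lineB)
  qd <- abs(sim$truth$qtn$freq_lineB - sim$truth$qtn$freq_lineA)
  expect_gte(qd, quantile(dd, 0.95, na.rm = TRUE))
})

test_that("neutral drift matches the pedigree-scale expectation", {
  # enlarged sequencing panels so the frequency estimates are not the
  # bottleneck; pure drift (zero QTN effect)
  p <- design_params(chrom_lengths = 6e5, qtn_effects = 0, seed = 33,
                     n_sample_lineA = 40L, n_sample_lineB = 40L, n_f1 = 2L)
  sim <- simulate_design(p)
  fr <- allele_frequencies(sim$genotypes)
  nA <- 80; nB <- 80
  pA <- fr$freq_lineA; pB <- fr$freq_lineB
  num <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  den <- pA * (1 - pB) + pB * (1 - pA)
  fst <- sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE)
  # pedigree scale: 20 sires + 60 dams per line per generation; truncation
  # selection depresses Ne early, equalized family contributions during
  # maintenance raise it towards twice the census (Ne roughly 60-300),
  # over 35 generations
  lo <- 1 - (1 - 1 / (2 * 300))^35
  hi <- 1 - (1 - 1 / (2 * 60))^35
  expect_gt(fst, lo)
  expect_lt(fst, hi)
})

test_that("companion fixtures carry the programmed signals", {
  p <- small_params()
  sim <- simulate_design(p)
  fx <- make_fixtures(sim$truth, p)
  # QTL intervals are +/- 6 Mb clipped to the chromosome
  expect_equal(fx$qtl$start, pmax(1L, as.integer(sim$truth$qtn$pos - 6e6)))
  expect_true(all(fx$qtl$end <= max(p$chrom_lengths)))
  # toy genes tile the QTN neighbourhood and some span the QTN
  expect_true(any(fx$genes$start <= sim$truth$qtn$pos &
                    fx$genes$end >= sim$truth$qtn$pos))
  # ASE table: programmed odds 0.6 recovered by the analysis pipeline
  res <- ase_analysis(fx$ase)
  expect_lt(abs(res$test$mean_ratio - 0.6), 0.05)
  # Ct table: the 1.4-cycle line effect gives the expected fold change
  expr <- relative_expression(fx$ct$ct_target, fx$ct$ct_reference)
  de <- differential_expression(expr[fx$ct$line == "lineB"],
                                expr[fx$ct$line == "lineA"])
  expect_lt(abs(log2(de$fold_change) - 1.4), 0.6)
  expect_lt(de$p, 0.01)
})

test_that("fixtures serialize to their standard formats and read back", {
  p <- small_params()
  sim <- simulate_design(p)
  fx <- make_fixtures(sim$truth, p)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(fx, dir)
  genes <- read_gene_models(paths[["genes"]])
  expect_equal(nrow(genes), nrow(fx$genes))
  expect_equal(genes$start, fx$genes$start)
  qtl <- read_qtl(paths[["qtl"]])
  expect_equal(qtl$start, fx$qtl$start)
  expect_equal(qtl$end, fx$qtl$end)
  ase <- tibble::as_tibble(read.delim(paths[["ase"]]))
  expect_equal(nrow(ase), nrow(fx$ase))
})

test_that("a balanced ASE fixture keeps the imbalance test calibrated", {
  p <- small_params()
  sim <- simulate_design(p)
  rej <- vapply(1:200, function(i) {
    fx <- make_fixtures(sim$truth, p, imbalance_odds = 1, seed = 1000 + i)
    ase_analysis(fx$ase)$test$p < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.12)
})
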