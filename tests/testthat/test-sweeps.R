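scan_tbl <- function(chrom, pos, q) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), q = q)
}

test_that("call_sweeps merges, bounds and filters regions as specified", {
  # no significant SNP -> empty
  empty <- call_sweeps(scan_tbl("chr1", c(1e5, 2e5), c(0.5, 0.9)))
  expect_equal(nrow(empty), 0)
  # three isolated significant singletons: all discarded (min 2 SNPs)
  lone <- call_sweeps(scan_tbl("chr1", c(1e5, 2e5, 3e5), c(0.01, 0.01, 0.01)),
                      merge_gap = 50000)
  expect_equal(nrow(lone), 0)
  # two clusters: 10.00/10.02/10.04 Mb and 12.00/12.01 Mb
  pos <- c(10e6, 10.02e6, 10.04e6, 12e6, 12.01e6)
  sw <- call_sweeps(scan_tbl("chr1", pos, rep(0.01, 5)), merge_gap = 50000)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$size_bp, c(40001L, 10001L))
  expect_equal(sw$n_snps_significant, c(3L, 2L))
  # n_snps_total counts every analyzed SNP inside the boundaries
  tab <- scan_tbl("chr1", c(10e6, 10.01e6, 10.02e6, 10.04e6),
                  c(0.01, 0.8, 0.01, 0.05))
  sw2 <- call_sweeps(tab, merge_gap = 50000)
  expect_equal(sw2$n_snps_total, 4L)
  expect_equal(sw2$n_snps_significant, 3L)
})

test_that("call_sweeps is invariant to input SNP order", {
  set.seed(30)
  tab <- scan_tbl(sample(c("chr1", "chr2"), 200, TRUE),
                  sample.int(5e6, 200), runif(200, 0, 0.4))
  tab <- tab[!duplicated(tab[c("chrom", "pos")]), ]
  a <- call_sweeps(tab)
  b <- call_sweeps(tab[sample.int(nrow(tab)), ])
  expect_equal(a, b)
})

test_that("gene annotation matches brute-force interval checks", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(100, 5000, 9000, 100, 700), end = c(900, 6000, 12000, 600, 1000))
  regions <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                            start = c(850L, 2000L, 650L),
                            end = c(5500L, 2500L, 710L))
  ann <- annotate_genes(regions, genes)
  # brute force
  for (i in seq_len(nrow(regions))) {
    want <- genes$gene_id[genes$chrom == regions$chrom[i] &
                            genes$start <= regions$end[i] &
                            genes$end >= regions$start[i]]
    expect_setequal(ann$genes[[i]], want)
  }
  expect_equal(ann$n_genes, c(2L, 0L, 1L))
})

test_that("annotate_genes reads GFF3 and honours partial overlap", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1000\t5000\t.\t+\t.\tID=geneX",
    "chr1\ttoy\tgene\t8000\t9000\t.\t-\t.\tID=geneY"), gff)
  regions <- tibble::tibble(chrom = "chr1", start = 4500L, end = 6000L)
  ann <- annotate_genes(regions, gff)
  expect_equal(ann$genes[[1]], "geneX")  # exon-3-only style partial overlap
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\ttoy\tgene\tnot_a_number\t5\t.\t+\t."),
             bad)
  expect_error(suppressWarnings(read_gene_models(bad)), "malformed")
})

test_that("per-chromosome summary and overall rows follow the conventions", {
  regions <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1e6L, 3e6L, 2e6L), end = c(2e6L - 1L, 3.5e6L - 1L, 2.2e6L - 1L),
    size_bp = c(1e6, 0.5e6, 0.2e6),
    n_snps_total = c(100L, 50L, 30L), n_snps_significant = c(10L, 5L, 3L),
    n_genes = c(2L, 0L, 1L))
  chrom_sizes <- tibble::tibble(chrom = c("chr1", "chr2", "chr3"),
                                size_bp = c(100e6, 50e6, 50e6))
  per <- summarize_by_chromosome(regions, chrom_sizes)
  expect_equal(per$coverage_pct[per$chrom == "chr1"], 1.5)
  expect_equal(per$coverage_pct[per$chrom == "chr2"], 0.4)
  ov <- overall_sweep_summary(per, genome_size_mb = 200)
  # coverage is bp-weighted: (1.5*100 + 0.4*50)/200
  expect_equal(ov$coverage_pct, (1.5 * 100 + 0.4 * 50) / 200)
  # unweighted mean of per-chromosome means
  expect_equal(ov$mean_size_kb, mean(c(750, 200)))
  expect_equal(ov$weighted_mean_size_kb, (2 * 750 + 1 * 200) / 3)
  expect_error(summarize_by_chromosome(
    dplyr::mutate(regions, chrom = "chrZ"), chrom_sizes), "chrZ")
})

test_that("published per-chromosome summary reproduces its overall row", {
  tab <- read.delim(system.file("extdata", "chicken_sweep_summary.tsv",
                                package = "hapsweep"))
  ov <- overall_sweep_summary(tab, genome_size_mb = 1050.9)
  expect_equal(round(ov$coverage_pct, 2), 1.36)
  expect_equal(round(ov$mean_size_kb, 2), 97.54)
  expect_equal(round(ov$mean_snps_per_sweep), 838)
  # the genes-per-sweep overall mean is printed slightly below the
  # recomputed unweighted mean (2.15); agreement is approximate only
  expect_lt(abs(ov$mean_genes_per_sweep - 2.11), 0.05)
  expect_equal(ov$n_sweeps, 129L)
})

test_that("QTL overlap uses inclusive-interval intersection", {
  qtls <- tibble::tibble(id = c("q1", "q2"), chrom = c("chr1", "chr1"),
                         start = c(1e6L, 5e6L), end = c(2e6L, 6e6L))
  regions <- tibble::tibble(chrom = "chr1", start = c(1.5e6L, 2000001L),
                            end = c(1.6e6L, 2100000L),
                            size_bp = c(100001L, 100000L))
  ov <- overlap_qtl(regions, qtls)
  # inside -> colocalized; abutting at end+1 -> not
  expect_equal(sum(!is.na(ov$sweep_start[ov$qtl_id == "q1"])), 1)
  expect_true(all(is.na(ov$sweep_start[ov$qtl_id == "q2"])))
  expect_equal(attr(ov, "n_colocalized"), 1)
})

test_that("published QTL/sweep table reconstructs the per-QTL counts", {
  tab <- read.delim(system.file("extdata", "chicken_qtl_sweeps.tsv",
                                package = "hapsweep"))
  qtls <- unique(tab[c("qtl_id", "chrom", "qtl_start_mb", "qtl_end_mb")])
  qtls <- tibble::tibble(id = qtls$qtl_id, chrom = paste0("chr", qtls$chrom),
                         start = as.integer(qtls$qtl_start_mb * 1e6),
                         end = as.integer(qtls$qtl_end_mb * 1e6))
  sweeps <- tibble::tibble(chrom = paste0("chr", tab$chrom),
                           start = as.integer(tab$sweep_start_mb * 1e6),
                           end = as.integer(tab$sweep_end_mb * 1e6 + 1),
                           size_bp = NA_integer_)
  ov <- overlap_qtl(sweeps, qtls)
  counts <- table(ov$qtl_id[!is.na(ov$sweep_start)])
  expect_equal(as.integer(counts[c("AF3.I", "AF3.II", "AF5", "AF7")]),
               c(5L, 3L, 1L, 1L))
  expect_equal(attr(ov, "n_colocalized"), 4)
})

test_that("coverage enrichment reproduces a hand-built 2x2 chi-square", {
  # genome 100 Mb, QTL 10 Mb, sweeps 1 Mb of which 0.5 Mb inside QTL
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(1e6L, 50e6L), end = c(1.5e6L - 1L, 50.5e6L - 1L))
  qtls <- tibble::tibble(id = "q", chrom = "chr1", start = 1e6L, end = 11e6L - 1L)
  enr <- coverage_enrichment(regions, qtls, genome_size_bp = 100e6)
  expect_equal(enr$cov_genome_pct, 1)
  expect_equal(enr$cov_qtl_pct, 5)
  tab <- matrix(c(0.5e6, 9.5e6, 0.5e6, 89.5e6), 2)
  want <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(enr$chi2, unname(want$statistic))
  expect_equal(enr$p, want$p.value)
  expect_error(coverage_enrichment(regions, qtls[0, ], 100e6), "empty")
})

test_that("uniformly spread sweeps show no QTL enrichment", {
  set.seed(31)
  starts <- sort(sample.int(99e6, 200))
  regions <- tibble::tibble(chrom = "chr1", start = starts,
                            end = starts + 4999L)
  qtls <- tibble::tibble(id = "q", chrom = "chr1",
                         start = 40e6L, end = 60e6L)
  enr <- coverage_enrichment(regions, qtls, genome_size_bp = 100e6)
  # coverages agree; the bp-level chi-square is astronomically powered, so
  # only the effect size is meaningful under the null
  expect_equal(enr$cov_qtl_pct, enr$cov_genome_pct, tolerance = 0.35)
})

test_that("expected sweep size is 1/(n rho T)", {
  expect_equal(expected_sweep_size(10, 3e-8, 35), 1 / (10 * 3e-8 * 35))
  expect_equal(round(expected_sweep_size(10, 3e-8, 35) / 1000), 95)
  expect_equal(expected_sweep_size(20, 3e-8, 35),
               expected_sweep_size(10, 3e-8, 35) / 2)
  expect_equal(expected_sweep_size(20, 1e-8, 50), 1e5)
  expect_error(expected_sweep_size(-1, 1e-8, 10), "> 0")
})

test_that("sweep BED export round-trips through the 0-based convention", {
  regions <- tibble::tibble(chrom = "chr1", start = c(1001L, 5001L),
                            end = c(2000L, 6000L), size_bp = c(1000L, 1000L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sweeps_bed(regions, path)
  back <- read_qtl(path)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
})
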