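# The toy setting (helper-fixtures.R): chrT = "ACGTACGT...", gene A on the
# plus strand with CDS 31..50 + 81..120, gene B on the minus strand with
# CDS 211..252.

test_that("SNP site classes follow the gene model geometry", {
  ann <- toy_annotation()
  base_at <- function(p) substr(ann$genome$chrT, p, p)
  snp <- function(pos, alt) tibble::tibble(chrom = "chrT", pos = pos,
                                           ref = base_at(pos), alt = alt)
  cls <- function(pos, alt) {
    as.character(classify_snps(snp(pos, alt), ann$transcripts,
                               ann$genome)$category)
  }
  expect_equal(cls(5, "T"), "intergenic")
  expect_equal(cls(150, "T"), "intergenic")   # downstream of gene A
  expect_equal(cls(65, "A"), "intronic")      # middle of the intron
  expect_equal(cls(25, "T"), "UTR")           # exon 1 before the CDS
  expect_equal(cls(125, "T"), "UTR")          # exon 2 after the CDS
  # essential splice region: 2 intronic bp beyond each exon edge
  expect_equal(cls(51, "T"), "splice_site")
  expect_equal(cls(52, "T"), "splice_site")
  expect_equal(cls(79, "T"), "splice_site")
  expect_equal(cls(80, "T"), "splice_site")
  expect_equal(cls(53, "T"), "intronic")
})

test_that("coding changes are translated codon-by-codon, strand-aware", {
  ann <- toy_annotation()
  base_at <- function(p) substr(ann$genome$chrT, p, p)
  one <- function(pos, alt) {
    classify_snps(tibble::tibble(chrom = "chrT", pos = pos,
                                 ref = base_at(pos), alt = alt),
                  ann$transcripts, ann$genome)
  }
  # plus-strand CDS starts at 31 in the ACGT repeat, so codon 1 is GTA
  # (Val); any third-position change keeps Val: synonymous
  res <- one(33, "T")
  expect_equal(as.character(res$category), "synonymous")
  # first position 31: G -> C gives CTA (Leu): missense
  expect_equal(as.character(one(31, "C")$category), "missense")
  # codon 4 is TAC (Tyr, genomic 40..42); TAC -> TAA is a gained stop
  expect_equal(as.character(one(42, "A")$category), "stop_gained")
  expect_match(one(42, "A")$codon_change, "\\*")
  # minus strand gene B: genomic 252 is the first CDS base read on -
  # strand; the genome is an ACGT repeat, so base 252 is T (complement A).
  resB <- one(214, "A")
  expect_equal(resB$gene_id, "geneB")
  expect_true(as.character(resB$category) %in%
                c("synonymous", "missense", "stop_gained", "stop_lost"))
  # reference mismatch is a data-consistency error naming the position
  expect_error(classify_snps(tibble::tibble(chrom = "chrT", pos = 10,
                                            ref = "G", alt = "A"),
                             ann$transcripts, ann$genome),
               "mismatch.*chrT:10")
})

test_that("every CDS classification agrees with full-CDS translation", {
  ann <- toy_annotation()
  tx <- ann$transcripts[ann$transcripts$gene_id == "geneA", ]
  cds <- tx[tx$type == "CDS", ]
  cds_pos <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
  seqs <- ann$genome$chrT
  cds_seq <- paste(vapply(cds_pos, function(p) substr(seqs, p, p),
                          character(1)), collapse = "")
  translate_chr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  set.seed(50)
  for (pos in sample(cds_pos, 12)) {
    ref <- substr(seqs, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_snps(tibble::tibble(chrom = "chrT", pos = pos,
                                        ref = ref, alt = alt),
                         ann$transcripts, ann$genome)
    idx <- match(pos, cds_pos)
    mut_seq <- cds_seq
    substr(mut_seq, idx, idx) <- alt
    aa_ref <- translate_chr(cds_seq)
    aa_alt <- translate_chr(mut_seq)
    brute <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
    cat_got <- as.character(got$category)
    if (brute == "synonymous") {
      expect_equal(cat_got, "synonymous")
    } else {
      expect_true(cat_got %in% c("missense", "stop_gained", "stop_lost",
                                 "start_lost"))
    }
  }
})

test_that("consequences are invariant under reverse-complementing the locus", {
  # gene B mirrored to the plus strand of a reverse-complemented genome
  ann <- toy_annotation()
  L <- nchar(ann$genome$chrT)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ann$genome$chrT)))
  txB <- ann$transcripts[ann$transcripts$gene_id == "geneB", ]
  txB_rc <- txB
  txB_rc$strand <- "+"
  txB_rc$start <- L - txB$end + 1
  txB_rc$end <- L - txB$start + 1
  set.seed(51)
  for (pos in sample(seq(205, 255), 8)) {
    ref <- substr(ann$genome$chrT, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    orig <- classify_snps(tibble::tibble(chrom = "chrT", pos = pos,
                                         ref = ref, alt = alt),
                          txB, ann$genome)
    pos_rc <- L - pos + 1
    comp <- function(b) chartr("ACGT", "TGCA", b)
    mirr <- classify_snps(tibble::tibble(chrom = "chrT", pos = pos_rc,
                                         ref = comp(ref), alt = comp(alt)),
                          txB_rc, list(chrT = rc))
    expect_equal(as.character(orig$category), as.character(mirr$category))
  }
})

test_that("most-severe rule resolves multi-transcript SNPs", {
  ann <- toy_annotation()
  # add a second transcript of gene A whose intron covers position 33
  tx2 <- tibble::tibble(transcript_id = "tA.2", gene_id = "geneA",
                        chrom = "chrT", strand = "+",
                        type = c("exon", "CDS", "exon", "CDS"),
                        start = c(21, 31, 101, 101), end = c(32, 32, 130, 129))
  # tA.2: CDS pieces 31..32 + 101..129 (2 + 29 = 31bp, not /3) -> adjust
  tx2$end[tx2$type == "CDS" & tx2$start == 101] <- 131
  tx2$end[tx2$type == "exon" & tx2$start == 101] <- 134
  both <- rbind(ann$transcripts, tx2)
  res <- classify_snps(tibble::tibble(chrom = "chrT", pos = 34,
                                      ref = substr(ann$genome$chrT, 34, 34),
                                      alt = "A"),
                       both, ann$genome)
  # in tA.1 position 34 is coding; in tA.2 it is the +2 splice base, which
  # outranks every coding class
  expect_equal(as.character(res$category), "splice_site")
  expect_equal(res$transcript_id, "tA.2")
})

test_that("tallies count by class with stable proportions", {
  cons <- tibble::tibble(category = factor(
    c("intergenic", "intergenic", "intronic", "intronic", "synonymous",
      "missense"), levels = hapsweep:::CONSEQUENCE_LEVELS))
  tal <- tally_consequences(cons)
  all_part <- tal[tal$breakdown == "all", ]
  expect_equal(sum(all_part$prop), 1)
  expect_equal(all_part$prop[all_part$category == "intergenic"], 2 / 6)
  cod <- tal[tal$breakdown == "coding", ]
  expect_equal(sum(cod$prop), 1)
  expect_equal(cod$prop[cod$category == "synonymous"], 0.5)
  expect_equal(nrow(tally_consequences(cons[0, ])), 0)
  # simulated class probabilities are recovered within binomial error
  set.seed(52)
  probs <- c(intergenic = 0.5, intronic = 0.4, synonymous = 0.1)
  draw <- tibble::tibble(category = sample(names(probs), 4000, TRUE, probs))
  tal2 <- tally_consequences(draw)
  got <- tal2$prop[tal2$breakdown == "all"][match(names(probs),
    tal2$category[tal2$breakdown == "all"])]
  expect_equal(got, unname(probs), tolerance = 0.05)
})
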