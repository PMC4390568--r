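#' Genotype container for biallelic SNP dosages
#'
#' Holds alt-allele dosages (0/1/2, `NA` for missing) for a set of
#' individuals with population labels, plus per-SNP coordinates and alleles.
#' Positions must be strictly increasing within each chromosome.
#'
#' @param snps Tibble with columns `chrom`, `pos` (1-based bp), `ref`, `alt`.
#' @param samples Tibble with columns `id` and `population` (e.g. `"lineA"`,
#'   `"lineB"`, `"F1"`).
#' @param dosage Integer matrix, individuals in rows (order of `samples`),
#'   SNPs in columns (order of `snps`); entries in `{0,1,2,NA}`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(snps, samples, dosage) {
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(
    all(c("chrom", "pos") %in% names(snps)),
    all(c("id", "population") %in% names(samples)),
    nrow(dosage) == nrow(samples),
    ncol(dosage) == nrow(snps)
  )
  if (!all(dosage %in% c(0L, 1L, 2L, NA_integer_))) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }
  bad <- snps |>
    group_by(.data$chrom) |>
    summarise(sorted = all(diff(.data$pos) > 0)) |>
    filter(!.data$sorted)
  if (nrow(bad) > 0) {
    abort(paste0("positions not strictly increasing on chromosome ",
                 bad$chrom[[1]]))
  }
  rownames(dosage) <- samples$id
  structure(list(snps = snps, samples = samples, dosage = dosage),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs\n",
              nrow(x$samples), nrow(x$snps)))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  chromosomes:",
      paste(unique(x$snps$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$samples), nrow(x$snps))

#' Long-format view of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per individual x SNP: `id`, `population`,
#'   `chrom`, `pos`, `dosage`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble(
    id = rep(x$samples$id, times = nrow(x$snps)),
    population = rep(x$samples$population, times = nrow(x$snps)),
    chrom = rep(x$snps$chrom, each = nrow(x$samples)),
    pos = rep(x$snps$pos, each = nrow(x$samples)),
    dosage = as.integer(x$dosage)
  )
}

#' Subset a genotype matrix by SNP index
#'
#' @param g A [geno_matrix()].
#' @param idx Integer or logical index over SNPs (columns).
#' @return A [geno_matrix()] with the selected SNPs, order preserved.
#' @export
subset_snps <- function(g, idx) {
  geno_matrix(g$snps[idx, , drop = FALSE], g$samples,
              g$dosage[, idx, drop = FALSE])
}

#' Read a population map
#'
#' Two-column TSV (sample id, population label), no header required.
#'
#' @param path File path.
#' @return Named character vector mapping sample id to label.
#' @export
read_population_map <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "id") ||
      identical(tolower(tab[1, 1]), "sample")) {
    tab <- tab[-1, , drop = FALSE]
  }
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

as_population_map <- function(population_map) {
  if (is.character(population_map) && !is.null(names(population_map))) {
    return(population_map)
  }
  if (is.data.frame(population_map)) {
    return(setNames(as.character(population_map[[2]]),
                    as.character(population_map[[1]])))
  }
  if (is.character(population_map) && length(population_map) == 1 &&
      file.exists(population_map)) {
    return(read_population_map(population_map))
  }
  abort("population_map must be a named vector, two-column data frame, or TSV path")
}

#' Read SNP genotypes from a VCF
#'
#' Keeps biallelic SNP records only; multiallelic and indel records are
#' dropped with an informative message. Only the GT field is used.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param population_map Named character vector `sample -> label`, a
#'   two-column data frame, or a path to a two-column TSV.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, population_map) {
  population_map <- as_population_map(population_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | alt == "*")
  keep <- !multi & !indel
  if (any(multi)) {
    inform(sprintf("read_vcf: excluded %d multiallelic record(s)", sum(multi)))
  }
  if (any(indel)) {
    inform(sprintf("read_vcf: excluded %d indel record(s)", sum(indel)))
  }
  samples_in_vcf <- colnames(v@gt)[-1]
  missing_map <- setdiff(samples_in_vcf, names(population_map))
  if (length(missing_map) > 0) {
    abort(paste0("sample(s) absent from population_map: ",
                 paste(missing_map, collapse = ", ")))
  }
  chrom <- fix$CHROM[keep]
  pos <- as.integer(fix$POS[keep])
  # VCFs must be coordinate-sorted; report the first offending record.
  off <- which(chrom[-1] == chrom[-length(chrom)] & diff(pos) <= 0)
  if (length(off) > 0) {
    abort(sprintf("VCF not sorted: %s:%d follows %s:%d",
                  chrom[off[1] + 1], pos[off[1] + 1],
                  chrom[off[1]], pos[off[1]]))
  }
  gt <- v@gt[keep, -1, drop = FALSE]
  gt <- sub(":.*", "", gt)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | a2 == ""] <- NA_integer_
  dosage <- t(matrix(as.integer(dos), nrow = sum(keep)))
  geno_matrix(
    snps = tibble(chrom = chrom, pos = pos, ref = ref[keep], alt = alt[keep]),
    samples = tibble(id = samples_in_vcf,
                     population = unname(population_map[samples_in_vcf])),
    dosage = dosage
  )
}

#' Write a genotype matrix as VCF
#'
#' @param g A [geno_matrix()].
#' @param path Output path; vcfR appends gzip compression, so a `.vcf.gz`
#'   suffix is conventional.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  S <- nrow(g$snps)
  fix <- cbind(
    CHROM = as.character(g$snps$chrom),
    POS = as.character(g$snps$pos),
    ID = rep(".", S),
    REF = if ("ref" %in% names(g$snps)) g$snps$ref else rep("A", S),
    ALT = if ("alt" %in% names(g$snps)) g$snps$alt else rep("C", S),
    QUAL = rep(".", S),
    FILTER = rep(".", S),
    INFO = rep(".", S)
  )
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosage
  gt_chr <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt_chr[ok] <- code[as.character(d[ok])]
  gt <- cbind(FORMAT = rep("GT", S), t(gt_chr))
  colnames(gt) <- c("FORMAT", g$samples$id)
  v <- methods::new("vcfR",
                    meta = c("##fileformat=VCFv4.2",
                             "##source=hapsweep",
                             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                                    "Description=\"Genotype\">")),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Per-SNP allele frequencies, MAF and call rate
#'
#' Alt-allele frequencies are computed per founder-line population
#' (individuals labelled with `f1_label` are excluded from the per-population
#' columns, matching the study design in which crossbreds enter haplotype
#' inference but not line frequencies). The minor-allele frequency and call
#' rate are computed over all individuals.
#'
#' @param g A [geno_matrix()].
#' @param f1_label Population label excluded from per-population frequencies
#'   (default `"F1"`).
#' @return Tibble with columns `chrom`, `pos`, one `freq_<pop>` column per
#'   founder population, `maf`, `call_rate`. A population with zero
#'   non-missing calls at a SNP yields `NA` frequency there.
#' @export
allele_frequencies <- function(g, f1_label = "F1") {
  d <- g$dosage
  pops <- setdiff(unique(g$samples$population), f1_label)
  out <- tibble(chrom = g$snps$chrom, pos = g$snps$pos)
  for (p in pops) {
    rows <- g$samples$population == p
    dp <- d[rows, , drop = FALSE]
    ncall <- colSums(!is.na(dp))
    f <- colSums(dp, na.rm = TRUE) / (2 * ncall)
    f[ncall == 0] <- NA_real_
    out[[paste0("freq_", p)]] <- f
  }
  ncall_all <- colSums(!is.na(d))
  f_all <- colSums(d, na.rm = TRUE) / (2 * ncall_all)
  f_all[ncall_all == 0] <- NA_real_
  out$maf <- pmin(f_all, 1 - f_all)
  out$call_rate <- ncall_all / nrow(d)
  out
}

#' Remove low-frequency SNPs
#'
#' Drops SNPs with minor-allele frequency strictly below `maf_min`
#' (a SNP at exactly the threshold is retained) and SNPs for which any
#' founder population has no genotyped individual.
#'
#' @param g A [geno_matrix()].
#' @param freq Output of [allele_frequencies()] computed on `g`.
#' @param maf_min MAF threshold (default 0.10).
#' @return Filtered [geno_matrix()], SNP order preserved.
#' @export
filter_maf <- function(g, freq = allele_frequencies(g), maf_min = 0.10) {
  stopifnot(nrow(freq) == nrow(g$snps))
  fcols <- grep("^freq_", names(freq), value = TRUE)
  pop_ok <- rowSums(is.na(freq[fcols])) == 0
  keep <- !is.na(freq$maf) & freq$maf >= maf_min & pop_ok
  if (sum(is.na(freq$maf) | !pop_ok) > 0) {
    inform(sprintf(
      "filter_maf: dropped %d SNP(s) with an entirely missing population",
      sum(is.na(freq$maf) | !pop_ok)))
  }
  if (!any(keep)) warn("filter_maf: no SNPs retained")
  subset_snps(g, which(keep))
}

#' Uniform SNP subsampling
#'
#' Draws `round(fraction * S)` SNPs uniformly without replacement,
#' reproducibly for a fixed seed, and keeps them in genomic order. The study
#' pipeline uses a 1% subsample for kinship estimation and a 30% subsample
#' for the haplotype scan.
#'
#' @param g A [geno_matrix()].
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Subsampled [geno_matrix()].
#' @export
subsample_snps <- function(g, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  S <- nrow(g$snps)
  if (fraction == 1) return(g)
  k <- round(fraction * S)
  idx <- sort(with_rng(seed, sample.int(S, k)))
  subset_snps(g, idx)
}

#' Whole-genome variant accounting summaries
#'
#' Turns raw discovery counts from a resequencing experiment into the
#' fractions and density usually quoted: the share of SNPs and indels typed
#' in every individual (100% call rate) and the per-individual SNP density.
#'
#' @param snps_total,snps_full_callrate Total discovered SNPs and the subset
#'   genotyped in all individuals.
#' @param indels_total,indels_full_callrate Same for indels.
#' @param snps_per_bird Mean number of SNPs observed within one individual.
#' @param genome_size_bp Genome size in bp.
#' @return One-row tibble: `snp_full_callrate_pct`, `indel_full_callrate_pct`,
#'   `snp_density_per_kb`.
#' @export
snp_accounting <- function(snps_total, snps_full_callrate,
                           indels_total, indels_full_callrate,
                           snps_per_bird, genome_size_bp) {
  tibble(
    snp_full_callrate_pct = 100 * snps_full_callrate / snps_total,
    indel_full_callrate_pct = 100 * indels_full_callrate / indels_total,
    snp_density_per_kb = snps_per_bird / (genome_size_bp / 1000)
  )
}
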