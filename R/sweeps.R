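#' Call sweep regions from a scored scan
#'
#' Significant SNPs (`q < q_threshold`) are grouped per chromosome;
#' consecutive significant SNPs separated by at most `merge_gap` bp fall in
#' the same region. Region boundaries are the outermost significant SNP
#' positions (1-based inclusive), and regions supported by fewer than two
#' significant SNPs are discarded.
#'
#' @param scan A `hapflk_scan` object or a tibble with `chrom`, `pos`, `q`.
#' @param q_threshold Significance cutoff (default 0.1).
#' @param merge_gap Maximum gap between significant SNPs inside one region
#'   (default 50000 bp, half the typical sweep size in a 35-generation
#'   divergent design).
#' @param min_snps Minimum significant SNPs per region (default 2).
#' @return Tibble of regions: `chrom`, `start`, `end`, `size_bp`,
#'   `n_snps_total` (analyzed SNPs within the boundaries),
#'   `n_snps_significant`.
#' @export
call_sweeps <- function(scan, q_threshold = 0.1, merge_gap = 50000,
                        min_snps = 2L) {
  tab <- if (inherits(scan, "hapflk_scan")) scan$table else as_tibble(scan)
  stopifnot(all(c("chrom", "pos", "q") %in% names(tab)))
  tab <- arrange(tab, .data$chrom, .data$pos)
  sig <- filter(tab, !is.na(.data$q), .data$q < q_threshold)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  size_bp = integer(), n_snps_total = integer(),
                  n_snps_significant = integer()))
  }
  regions <- sig |>
    group_by(.data$chrom) |>
    mutate(new_region = c(TRUE, diff(.data$pos) > merge_gap),
           region = cumsum(.data$new_region)) |>
    group_by(.data$chrom, .data$region) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_snps_significant = n(), .groups = "drop") |>
    filter(.data$n_snps_significant >= min_snps) |>
    select(-"region")
  regions$n_snps_total <- purrr::pmap_int(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sum(tab$chrom == chrom & tab$pos >= start & tab$pos <= end)
    })
  regions |>
    mutate(size_bp = .data$end - .data$start + 1L) |>
    select("chrom", "start", "end", "size_bp",
           "n_snps_total", "n_snps_significant") |>
    arrange(.data$chrom, .data$start)
}

intervals_to_gr <- function(tbl) {
  GenomicRanges::GRanges(tbl$chrom,
                         IRanges::IRanges(tbl$start, tbl$end))
}

#' Read gene models (gene features) from a GFF3 file
#'
#' @param path GFF3 file.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `strand` (1-based
#'   inclusive coordinates).
#' @export
read_gene_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(paste0("malformed GFF3 '", path, "': ",
                                conditionMessage(e)))
                 })
  genes <- gr[gr$type == "gene"]
  id <- genes$ID %||% genes$gene_id %||% as.character(seq_along(genes))
  tibble(gene_id = as.character(id),
         chrom = as.character(GenomicRanges::seqnames(genes)),
         start = GenomicRanges::start(genes),
         end = GenomicRanges::end(genes),
         strand = as.character(GenomicRanges::strand(genes)))
}

#' Attach overlapping genes to sweep regions
#'
#' A gene counts as overlapping when its span intersects the region at all
#' (partial overlap counts: a sweep may contain only a portion of a gene).
#'
#' @param regions Tibble of regions (`chrom`, `start`, `end`).
#' @param genes Gene tibble from [read_gene_models()], or a GFF3 path.
#' @return `regions` with list-column `genes` and count `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (nrow(regions) == 0) {
    regions$genes <- list()
    regions$n_genes <- integer()
    return(regions)
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(regions),
                                      intervals_to_gr(genes))
  gl <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions$genes <- unname(lapply(gl, as.character))
  regions$n_genes <- lengths(regions$genes)
  regions
}

#' Per-chromosome sweep summary
#'
#' One row per chromosome carrying a sweep: count, size statistics (kb),
#' coverage percent, SNPs-per-sweep and genes-per-sweep statistics —
#' the classic genome-wide description table of a sweep scan.
#'
#' @param regions Tibble of sweep regions (with `n_snps_total`; `n_genes`
#'   used when present).
#' @param chrom_sizes Tibble `chrom`, `size_bp` covering at least every
#'   chromosome with a region (chromosomes without sweeps still count in
#'   the genome size).
#' @return Tibble with per-chromosome rows; overall summaries via
#'   [overall_sweep_summary()].
#' @export
summarize_by_chromosome <- function(regions, chrom_sizes) {
  missing_chr <- setdiff(unique(regions$chrom), chrom_sizes$chrom)
  if (length(missing_chr) > 0) {
    abort(paste0("chromosome(s) missing from chrom_sizes: ",
                 paste(missing_chr, collapse = ", ")))
  }
  has_genes <- "n_genes" %in% names(regions)
  per <- regions |>
    group_by(.data$chrom) |>
    summarise(
      n_sweeps = n(),
      mean_kb = mean(.data$size_bp) / 1000,
      min_kb = min(.data$size_bp) / 1000,
      max_kb = max(.data$size_bp) / 1000,
      sweep_bp = sum(.data$size_bp),
      snps_mean = mean(.data$n_snps_total),
      snps_min = min(.data$n_snps_total),
      snps_max = max(.data$n_snps_total),
      genes_mean = if (has_genes) mean(.data$n_genes) else NA_real_,
      genes_total = if (has_genes) sum(.data$n_genes) else NA_integer_,
      .groups = "drop")
  per <- left_join(per, chrom_sizes, by = "chrom") |>
    mutate(chrom_size_mb = .data$size_bp / 1e6,
           coverage_pct = 100 * .data$sweep_bp / .data$size_bp) |>
    select(-"size_bp")
  per
}

#' Overall sweep summary from a per-chromosome table
#'
#' The overall coverage is the size-weighted combination
#' `sum(coverage_c * size_c) / genome_size`; the overall mean sweep size,
#' SNPs/sweep and genes/sweep are reported both as unweighted means of the
#' per-chromosome means (the convention of the classic summary table) and
#' as sweep-count-weighted means.
#'
#' @param per_chrom Tibble with columns `chrom_size_mb`, `coverage_pct`,
#'   `mean_kb`, `snps_mean` and optionally `genes_mean`, `n_sweeps` — e.g.
#'   from [summarize_by_chromosome()] or a published summary table.
#' @param genome_size_mb Total genome size in Mb (defaults to the sum of
#'   the table's chromosome sizes; pass the full genome size when the table
#'   omits sweep-free chromosomes).
#' @return One-row tibble: `n_sweeps`, `coverage_pct`, `mean_size_kb`,
#'   `mean_snps_per_sweep`, `mean_genes_per_sweep` (unweighted means of
#'   per-chromosome means) and `weighted_mean_size_kb`,
#'   `weighted_mean_snps_per_sweep` (weighted by sweep counts, when
#'   available).
#' @export
overall_sweep_summary <- function(per_chrom, genome_size_mb = NULL) {
  genome_size_mb <- genome_size_mb %||% sum(per_chrom$chrom_size_mb)
  w <- if ("n_sweeps" %in% names(per_chrom)) per_chrom$n_sweeps else NULL
  wmean <- function(x) if (is.null(w)) NA_real_ else sum(x * w) / sum(w)
  tibble(
    n_sweeps = if (is.null(w)) NA_integer_ else sum(w),
    coverage_pct = sum(per_chrom$coverage_pct * per_chrom$chrom_size_mb) /
      genome_size_mb,
    mean_size_kb = mean(per_chrom$mean_kb),
    mean_snps_per_sweep = mean(per_chrom$snps_mean),
    mean_genes_per_sweep = if ("genes_mean" %in% names(per_chrom)) {
      mean(per_chrom$genes_mean)
    } else {
      NA_real_
    },
    weighted_mean_size_kb = wmean(per_chrom$mean_kb),
    weighted_mean_snps_per_sweep = wmean(per_chrom$snps_mean)
  )
}

#' Read QTL intervals
#'
#' Accepts a BED file (0-based half-open; converted to 1-based inclusive)
#' or a TSV with explicit 1-based `chrom`, `start`, `end` (+ optional `id`)
#' columns.
#'
#' @param path File path.
#' @return Tibble `id`, `chrom`, `start`, `end`.
#' @export
read_qtl <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    tibble(id = gr$name %||% paste0("qtl", seq_along(gr)),
           chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr),
           end = GenomicRanges::end(gr))
  } else {
    tab <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
    stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
    if (!"id" %in% names(tab)) tab$id <- paste0("qtl", seq_len(nrow(tab)))
    tab[c("id", "chrom", "start", "end")]
  }
}

#' Colocalize sweep regions with QTL intervals
#'
#' A sweep colocalizes with a QTL iff the 1-based inclusive intervals
#' intersect (a sweep starting one bp past the QTL end does not).
#'
#' @param regions Sweep region tibble (optionally gene-annotated).
#' @param qtls QTL tibble (`id`, `chrom`, `start`, `end`).
#' @return Tibble with one row per QTL x colocalized sweep (QTL without
#'   sweeps keep one row with `NA` sweep columns); attribute
#'   `n_colocalized` counts QTL hit by at least one sweep.
#' @export
overlap_qtl <- function(regions, qtls) {
  stopifnot(all(qtls$start < qtls$end))
  rows <- purrr::pmap(qtls, function(id, chrom, start, end, ...) {
    hit <- regions$chrom == chrom & regions$start <= end & regions$end >= start
    if (!any(hit)) {
      return(tibble(qtl_id = id, chrom = chrom, qtl_start = start,
                    qtl_end = end, sweep_start = NA_integer_,
                    sweep_end = NA_integer_, sweep_size_bp = NA_integer_,
                    sweep_genes = list(NULL)))
    }
    r <- regions[hit, ]
    tibble(qtl_id = id, chrom = chrom, qtl_start = start, qtl_end = end,
           sweep_start = r$start, sweep_end = r$end,
           sweep_size_bp = r$size_bp,
           sweep_genes = if ("genes" %in% names(r)) r$genes
                         else replicate(nrow(r), NULL, simplify = FALSE))
  })
  out <- bind_rows(rows)
  attr(out, "n_colocalized") <-
    length(unique(out$qtl_id[!is.na(out$sweep_start)]))
  out
}

# total bp of the union of a set of 1-based inclusive intervals
union_bp <- function(tbl) {
  if (nrow(tbl) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(intervals_to_gr(tbl))))
}

#' Sweep coverage enrichment inside QTL
#'
#' Compares the fraction of the genome covered by sweeps with the fraction
#' of the (union of) QTL intervals covered by sweeps, using a Pearson
#' chi-square test on the 2x2 table of bp counts
#' \{sweep, non-sweep\} x \{QTL, non-QTL\}.
#'
#' @param regions Sweep region tibble.
#' @param qtls QTL tibble.
#' @param genome_size_bp Total genome size in bp.
#' @return One-row tibble: `cov_genome_pct`, `cov_qtl_pct`, `chi2`, `p`,
#'   plus the underlying bp counts.
#' @export
coverage_enrichment <- function(regions, qtls, genome_size_bp) {
  if (nrow(qtls) == 0) abort("coverage_enrichment: empty QTL set")
  sweep_bp <- union_bp(regions)
  qtl_bp <- union_bp(qtls)
  in_gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(intervals_to_gr(regions)),
    GenomicRanges::reduce(intervals_to_gr(qtls)))
  sweep_in_qtl <- sum(GenomicRanges::width(in_gr))
  tab <- matrix(c(sweep_in_qtl, qtl_bp - sweep_in_qtl,
                  sweep_bp - sweep_in_qtl,
                  genome_size_bp - qtl_bp - (sweep_bp - sweep_in_qtl)),
                nrow = 2)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(cov_genome_pct = 100 * sweep_bp / genome_size_bp,
         cov_qtl_pct = 100 * sweep_in_qtl / qtl_bp,
         chi2 = unname(ct$statistic), p = ct$p.value,
         sweep_bp = sweep_bp, qtl_bp = qtl_bp,
         sweep_in_qtl_bp = sweep_in_qtl,
         genome_bp = genome_size_bp)
}

#' Expected sweep size under recurrent recombination
#'
#' The expected extent of a selected haplotype after `T` generations in a
#' sample of `n` haploid genomes is approximately `1 / (n * rho * T)` bp.
#'
#' @param n Haploid sample size.
#' @param rho Recombination rate per bp per generation.
#' @param T_gen Total number of generations.
#' @return Expected sweep size in bp.
#' @export
expected_sweep_size <- function(n, rho, T_gen) {
  if (any(c(n, rho, T_gen) <= 0)) abort("all parameters must be > 0")
  1 / (n * rho * T_gen)
}

#' Write sweep regions as BED
#'
#' @param regions Sweep region tibble (1-based inclusive).
#' @param path Output BED path (converted to 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_sweeps_bed <- function(regions, path) {
  gr <- intervals_to_gr(regions)
  gr$name <- paste0("sweep", seq_along(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
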