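# Consequence categories, least to most severe. A SNP hitting several
# transcripts gets the most severe category.
CONSEQUENCE_LEVELS <- c("intergenic", "intronic", "UTR", "synonymous",
                        "missense", "stop_gained", "stop_lost",
                        "start_lost", "splice_site")

#' Read transcript models from a GFF3 file
#'
#' Collects `exon` and `CDS` features grouped by transcript. Exons must be
#' non-overlapping within a transcript; CDS length must be divisible by 3.
#'
#' @param path GFF3 file with exon/CDS features carrying a `Parent` (or
#'   `transcript_id`) attribute.
#' @return Tibble with one row per feature: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `type` (`"exon"`/`"CDS"`), `start`, `end`.
#' @export
read_transcript_models <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   abort(paste0("malformed GFF3 '", path, "': ",
                                conditionMessage(e)))
                 })
  feat <- gr[gr$type %in% c("exon", "CDS")]
  parent <- as.character(S4Vectors::mcols(feat)$Parent)
  gene <- if (!is.null(feat$gene_id)) as.character(feat$gene_id) else parent
  tibble(transcript_id = parent,
         gene_id = gene,
         chrom = as.character(GenomicRanges::seqnames(feat)),
         strand = as.character(GenomicRanges::strand(feat)),
         type = as.character(feat$type),
         start = GenomicRanges::start(feat),
         end = GenomicRanges::end(feat))
}

# genome: named character vector or DNAStringSet of chromosome sequences
genome_base <- function(genome, chrom, pos) {
  substr(as.character(genome[[chrom]]), pos, pos)
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

# Classify one SNP against one transcript; returns list(category, codon_change)
classify_one <- function(pos, alt, tx, genome, chrom) {
  exons <- tx[tx$type == "exon", c("start", "end")]
  cds <- tx[tx$type == "CDS", c("start", "end")]
  strand <- tx$strand[1]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  span <- range(c(exons$start, exons$end))
  if (pos < span[1] || pos > span[2]) return(NULL)

  # essential splice region: the first/last 2 intronic bp of each intron
  if (nrow(exons) > 1) {
    donors <- exons$end[-nrow(exons)]
    acceptors <- exons$start[-1]
    if (any(pos >= donors + 1 & pos <= donors + 2) ||
        any(pos >= acceptors - 2 & pos <= acceptors - 1)) {
      return(list(category = "splice_site", codon_change = NA_character_))
    }
  }
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  if (!in_exon) return(list(category = "intronic", codon_change = NA_character_))
  in_cds <- nrow(cds) > 0 && any(pos >= cds$start & pos <= cds$end)
  if (!in_cds) return(list(category = "UTR", codon_change = NA_character_))

  # build the coding sequence and locate the SNP in it, strand-aware
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    substr(as.character(genome[[chrom]]), cds$start[i], cds$end[i])
  }, character(1))
  cds_seq <- paste(seqs, collapse = "")
  offsets <- cumsum(c(0, cds$end - cds$start + 1))
  seg <- which(pos >= cds$start & pos <= cds$end)[1]
  idx_plus <- offsets[seg] + (pos - cds$start[seg]) + 1
  if (strand == "-") {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
    idx <- nchar(cds_seq) - idx_plus + 1
    alt_b <- complement_base(alt)
  } else {
    idx <- idx_plus
    alt_b <- alt
  }
  if (nchar(cds_seq) %% 3 != 0) {
    abort(sprintf("CDS length of transcript %s not divisible by 3",
                  tx$transcript_id[1]))
  }
  codon_i <- (idx - 1) %/% 3
  pos_in <- (idx - 1) %% 3 + 1
  codon_ref <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  codon_alt <- codon_ref
  substr(codon_alt, pos_in, pos_in) <- toupper(alt_b)
  aa_ref <- Biostrings::GENETIC_CODE[[toupper(codon_ref)]]
  aa_alt <- Biostrings::GENETIC_CODE[[toupper(codon_alt)]]
  change <- paste0(codon_ref, ">", codon_alt, " (", aa_ref, ">", aa_alt, ")")
  category <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (codon_i == 0 && aa_ref == "M") {
    "start_lost"
  } else if (aa_alt == "*") {
    "stop_gained"
  } else if (aa_ref == "*") {
    "stop_lost"
  } else {
    "missense"
  }
  list(category = category, codon_change = change)
}

#' Classify SNPs by genic context and coding consequence
#'
#' For each SNP, each overlapping transcript contributes one category
#' (splice site within 2 intronic bp of an exon boundary; codon-level
#' classes inside the CDS via the standard genetic code, strand-aware;
#' UTR for exonic non-coding; intronic; intergenic otherwise) and the SNP
#' keeps the most severe one.
#'
#' @param snps Tibble `chrom`, `pos`, `ref`, `alt`.
#' @param transcripts Feature tibble from [read_transcript_models()] (or a
#'   GFF3 path).
#' @param genome Named list/character vector or `DNAStringSet` of
#'   chromosome sequences.
#' @return `snps` with `category` (factor ordered by severity), `gene_id`,
#'   `transcript_id`, `codon_change`.
#' @export
classify_snps <- function(snps, transcripts, genome) {
  if (is.character(transcripts) && length(transcripts) == 1) {
    transcripts <- read_transcript_models(transcripts)
  }
  tx_split <- split(transcripts, transcripts$transcript_id)
  res <- purrr::pmap(snps[c("chrom", "pos", "ref", "alt")],
                     function(chrom, pos, ref, alt) {
    gb <- genome_base(genome, chrom, pos)
    if (toupper(gb) != toupper(ref)) {
      abort(sprintf("reference mismatch at %s:%d (genome %s, stated %s)",
                    chrom, pos, gb, ref))
    }
    best <- NULL
    for (tx in tx_split) {
      if (tx$chrom[1] != chrom) next
      r <- classify_one(pos, alt, tx, genome, chrom)
      if (is.null(r)) next
      r$transcript_id <- tx$transcript_id[1]
      r$gene_id <- tx$gene_id[1]
      if (is.null(best) ||
          match(r$category, CONSEQUENCE_LEVELS) >
          match(best$category, CONSEQUENCE_LEVELS)) {
        best <- r
      }
    }
    if (is.null(best)) {
      best <- list(category = "intergenic", codon_change = NA_character_,
                   transcript_id = NA_character_, gene_id = NA_character_)
    }
    best
  })
  snps |>
    mutate(category = factor(purrr::map_chr(res, "category"),
                             levels = CONSEQUENCE_LEVELS),
           gene_id = purrr::map_chr(res, "gene_id"),
           transcript_id = purrr::map_chr(res, "transcript_id"),
           codon_change = purrr::map_chr(res, "codon_change"))
}

#' Tally consequence categories
#'
#' @param consequences Output of [classify_snps()] (or any tibble with a
#'   `category` column).
#' @return Tibble `breakdown` (`"all"` or `"coding"`), `category`, `n`,
#'   `prop`; proportions sum to 1 within each breakdown. The `"coding"`
#'   breakdown covers the coding-associated classes (synonymous, missense,
#'   start/stop changes, splice sites).
#' @export
tally_consequences <- function(consequences) {
  if (nrow(consequences) == 0) {
    return(tibble(breakdown = character(), category = character(),
                  n = integer(), prop = numeric()))
  }
  coding_classes <- c("synonymous", "missense", "stop_gained", "stop_lost",
                      "start_lost", "splice_site")
  all_tab <- consequences |>
    dplyr::count(.data$category, name = "n") |>
    mutate(breakdown = "all", prop = .data$n / sum(.data$n))
  coding <- filter(consequences, .data$category %in% coding_classes)
  out <- all_tab
  if (nrow(coding) > 0) {
    cod_tab <- coding |>
      dplyr::count(.data$category, name = "n") |>
      mutate(breakdown = "coding", prop = .data$n / sum(.data$n))
    out <- bind_rows(all_tab, cod_tab)
  }
  out |>
    mutate(category = as.character(.data$category)) |>
    select("breakdown", "category", "n", "prop")
}
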