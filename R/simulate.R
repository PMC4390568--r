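#' Parameters of the divergent-selection breeding design
#'
#' Defaults mirror the study design the simulator emulates: a founder stock
#' mixing six ancestral meat lines (23 sires, 68 dams), seven generations
#' of divergent truncation selection on an additive fatness trait, 28
#' further generations of maintenance with 20 sires per line, chicken-like
#' SNP density (2.6/kb) and recombination rate (3e-8 per bp per
#' generation).
#'
#' @param n_ancestral_lines Ancestral lines mixed in the founders.
#' @param founder_sires,founder_dams Founder counts.
#' @param selection_generations,maintenance_generations Phase lengths.
#' @param sires_per_generation,dams_per_generation Parents kept per line
#'   per generation after the founders.
#' @param selected_fraction Fraction of candidates kept as parents.
#' @param n_qtn Number of selected loci.
#' @param qtn_effects Additive allele substitution effect(s), recycled over
#'   QTNs (trait units; the polygenic background has unit standard
#'   deviation, so the default 3 is a major QTL of about two phenotypic
#'   standard deviations).
#' @param polygenic_sd Standard deviation of the infinitesimal polygenic
#'   component of the trait. The background keeps truncation selection
#'   from collapsing each line onto the first QTN-carrier family, as a
#'   monogenic trait would.
#' @param heritability Narrow-sense heritability of the trait in (0, 1].
#' @param recomb_rate Crossovers per bp per generation.
#' @param snp_density SNPs per kb.
#' @param chrom_lengths Chromosome lengths in bp.
#' @param founder_divergence Balding-Nichols F among ancestral lines.
#' @param within_line_diversity Per-SNP divergence of each prototype
#'   haplotype from its line consensus: ancestral lines are internally
#'   cohesive relative to the between-line divergence.
#' @param prototypes_per_line Ancestral haplotype prototypes per line
#'   (founder haplotypes are mosaics of these, which is what gives the
#'   founder population its cluster structure).
#' @param proto_switch_rate Per-bp prototype switch rate in founder mosaics.
#' @param founder_residual_het Per-SNP flip probability applied to each
#'   founder chromosome, giving residual within-line haplotype diversity
#'   so that founder chromosomes are not exact prototype copies.
#' @param n_sample_lineA,n_sample_lineB,n_f1 Birds sampled for sequencing.
#' @param seed Integer seed.
#' @return A `design_params` list.
#' @export
design_params <- function(n_ancestral_lines = 6L,
                          founder_sires = 23L, founder_dams = 68L,
                          selection_generations = 7L,
                          maintenance_generations = 28L,
                          sires_per_generation = 20L,
                          dams_per_generation = 60L,
                          selected_fraction = 0.25,
                          n_qtn = 1L, qtn_effects = 3,
                          polygenic_sd = 1,
                          heritability = 0.5,
                          recomb_rate = 3e-8,
                          snp_density = 2.6,
                          chrom_lengths = rep(10e6, 5),
                          founder_divergence = 0.2,
                          within_line_diversity = 0.02,
                          prototypes_per_line = 12L,
                          proto_switch_rate = 2e-5,
                          founder_residual_het = 0.01,
                          n_sample_lineA = 7L, n_sample_lineB = 4L,
                          n_f1 = 9L,
                          seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$heritability > 0, p$heritability <= 1,
            p$selected_fraction > 0, p$selected_fraction <= 1,
            all(p$chrom_lengths > 0))
  structure(p, class = "design_params")
}

# One gamete from a pair of parental haplotypes: crossovers are Poisson
# along the chromosome at `rate` per bp; the gamete alternates between the
# two haplotypes at the crossover points.
#' Simulate one meiosis
#'
#' @param h1,h2 Integer allele vectors of the parent's two haplotypes.
#' @param pos SNP positions (bp, increasing).
#' @param rate Crossover rate per bp.
#' @return Integer gamete vector; the number of crossovers drawn is
#'   attached as attribute `crossovers`.
#' @export
meiosis_gamete <- function(h1, h2, pos, rate) {
  L <- pos[length(pos)] - pos[1]
  nc <- rpois(1, rate * max(L, 0))
  first <- sample.int(2L, 1)
  if (nc == 0) {
    g <- if (first == 1) h1 else h2
  } else {
    cx <- sort(runif(nc, pos[1], pos[length(pos)]))
    seg <- (findInterval(pos, cx) + first) %% 2L
    g <- h1
    take2 <- seg == 0L
    g[take2] <- h2[take2]
  }
  attr(g, "crossovers") <- nc
  g
}

# All gametes one parent set contributes: parents[o] gives the individual
# index for offspring o. Crossover-free meioses (the vast majority at
# chicken-like rates) are bulk column copies.
gametes_for <- function(H, pos, parents, rate) {
  n_off <- length(parents)
  L <- pos[length(pos)] - pos[1]
  nc <- rpois(n_off, rate * max(L, 0))
  first <- sample.int(2L, n_off, replace = TRUE)
  G <- matrix(0L, nrow(H), n_off)
  zero <- nc == 0L
  if (any(zero)) {
    G[, zero] <- H[, 2L * (parents[zero] - 1L) + first[zero]]
  }
  for (o in which(!zero)) {
    cx <- sort(runif(nc[o], pos[1], pos[length(pos)]))
    seg <- (findInterval(pos, cx) + first[o]) %% 2L
    h1 <- H[, 2L * parents[o] - 1L]
    g <- H[, 2L * parents[o]]
    take1 <- seg == 1L
    g[take1] <- h1[take1]
    G[, o] <- g
  }
  G
}

# ---- founder pool ---------------------------------------------------------

make_founders_impl <- function(params) {
  n_founders <- params$founder_sires + params$founder_dams
  n_lines <- params$n_ancestral_lines
  Fdiv <- params$founder_divergence
  founder_line <- ((seq_len(n_founders) - 1L) %% n_lines) + 1L
  snps <- list(); haps <- list()
  for (c_i in seq_along(params$chrom_lengths)) {
    L <- params$chrom_lengths[c_i]
    S <- max(2L, rpois(1, params$snp_density * L / 1000))
    pos <- sort(sample.int(L, S))
    p_anc <- runif(S, 0.05, 0.95)
    # Balding-Nichols line frequencies around the shared ancestral frequency
    line_freq <- vapply(seq_len(n_lines), function(l) {
      if (Fdiv <= 0) return(p_anc)
      rbeta(S, p_anc * (1 - Fdiv) / Fdiv, (1 - p_anc) * (1 - Fdiv) / Fdiv)
    }, numeric(S))
    # Each ancestral line contributes a consensus haplotype (a draw from
    # its frequency profile) plus prototypes that deviate from it by a
    # small within-line diversity: lines are internally cohesive, so the
    # K = n_ancestral_lines cluster model premise holds in the founders.
    protos <- lapply(seq_len(n_lines), function(l) {
      cons <- rbinom(S, 1, line_freq[, l])
      vapply(seq_len(params$prototypes_per_line), function(j) {
        flip <- runif(S) < params$within_line_diversity
        ifelse(flip, 1L - cons, cons)
      }, integer(S))
    })
    d <- c(0, diff(pos))
    p_switch <- 1 - exp(-params$proto_switch_rate * d)
    H <- matrix(0L, S, 2L * n_founders)
    for (f in seq_len(n_founders)) {
      pr <- protos[[founder_line[f]]]
      P <- ncol(pr)
      for (h in 1:2) {
        switches <- runif(S) < p_switch
        switches[1] <- TRUE
        idx <- cumsum(switches)
        proto_draw <- sample.int(P, max(idx), replace = TRUE)
        hap <- pr[cbind(seq_len(S), proto_draw[idx])]
        # residual within-line diversity: no two founder chromosomes are
        # exact prototype copies
        if (params$founder_residual_het > 0) {
          flip <- runif(S) < params$founder_residual_het
          hap[flip] <- 1L - hap[flip]
        }
        H[, 2L * (f - 1L) + h] <- hap
      }
    }
    snps[[c_i]] <- tibble(chrom = paste0("chr", c_i), pos = pos)
    haps[[c_i]] <- H
  }
  list(snps = bind_rows(snps), snps_by_chrom = snps, haps = haps,
       founder_line = founder_line,
       sex = rep(c("M", "F"), c(params$founder_sires, params$founder_dams)))
}

#' Simulate the founder haplotype pool
#'
#' Each ancestral line gets a Balding-Nichols allele-frequency profile
#' around a shared ancestral frequency; founder haplotypes are mosaics of
#' line-specific prototype haplotypes (this creates the linkage structure
#' that the haplotype-cluster model summarizes). Founders are assigned to
#' lines round-robin.
#'
#' @param params A [design_params()].
#' @return List with `snps` (tibble `chrom`, `pos`), `haps` (per-chromosome
#'   S x 2N integer matrices), `founder_line`, `sex`.
#' @export
make_founders <- function(params) {
  with_rng(params$seed, make_founders_impl(params))
}

# ---- forward simulation ---------------------------------------------------

# Pick `k` individuals from `candidates` spreading the picks over the
# families defined by `family_of` (round-robin over families, shuffled
# within family): equalized family contributions limit inbreeding.
balanced_pick <- function(candidates, family_of, k) {
  if (length(candidates) < k) {
    abort("not enough candidates of one sex; increase selected_fraction")
  }
  perm <- sample(candidates)
  fam <- split(perm, family_of[perm])
  ord <- unlist(lapply(seq_len(max(lengths(fam))), function(i) {
    unlist(lapply(fam, function(x) if (length(x) >= i) x[i] else NULL))
  }), use.names = FALSE)
  ord[seq_len(k)]
}

# dosage of individual i at SNP row `row` of chromosome `c_i`
hap_dosage_row <- function(haps, c_i, row) {
  H <- haps[[c_i]]
  H[row, seq(1, ncol(H), by = 2)] + H[row, seq(2, ncol(H), by = 2)]
}

# genetic values for all individuals in a haplotype set
genetic_values <- function(haps, qtn) {
  n_ind <- ncol(haps[[1]]) / 2
  g <- numeric(n_ind)
  for (i in seq_len(nrow(qtn))) {
    g <- g + qtn$effect[i] *
      (hap_dosage_row(haps, qtn$chrom_index[i], qtn$row[i]) - 1)
  }
  g
}

# produce offspring haplotypes from chosen sire/dam columns
breed <- function(haps, pos_by_chrom, sires, dams, rate) {
  n_off <- length(sires)
  lapply(seq_along(haps), function(c_i) {
    H <- haps[[c_i]]
    pos <- pos_by_chrom[[c_i]]
    O <- matrix(0L, nrow(H), 2L * n_off)
    O[, seq(1L, 2L * n_off, by = 2L)] <- gametes_for(H, pos, sires, rate)
    O[, seq(2L, 2L * n_off, by = 2L)] <- gametes_for(H, pos, dams, rate)
    O
  })
}

#' Simulate the divergent-line design and sample birds for sequencing
#'
#' Forward-in-time Wright-Fisher simulation with pedigree: candidates each
#' generation are phenotyped (genetic value plus normal noise scaled to the
#' heritability) and truncation-selected — the low tail in line A (lean),
#' the high tail in line B (fat) — for `selection_generations`, then
#' parents are drawn at random during maintenance. Crossovers are Poisson
#' along each chromosome. At the final generation, F1 birds are produced by
#' crossing line-B sires with line-A dams, and the sequencing panel
#' (`n_sample_lineA` + `n_sample_lineB` + `n_f1` birds) is assembled.
#'
#' @param params A [design_params()].
#' @return List with `genotypes` (a [geno_matrix()] of the sampled birds)
#'   and `truth` (QTN table with final line frequencies, per-generation
#'   line means, per-generation pedigree summary, and `sigma_e`).
#' @export
simulate_design <- function(params) {
  with_rng(params$seed, simulate_design_impl(params))
}

simulate_design_impl <- function(params) {
  fo <- make_founders_impl(params)
  pos_by_chrom <- lapply(fo$snps_by_chrom, function(x) x$pos)
  n_chrom <- length(pos_by_chrom)

  # QTN: per selected locus, the SNP nearest the chromosome midpoint is
  # rewritten as a new mutation carried by a single founder-sire haplotype.
  # The favourable allele then rises from one copy on one haplotype
  # background, and its fixation drags that haplotype along — the
  # hard-sweep regime whose local footprint the scan is designed to
  # detect. (An allele starting from standing variation on many founder
  # backgrounds sweeps softly and leaves almost no haplotype signature
  # over the drift noise of a small-Ne design.) A founder sire carries the
  # copy because sires sire many offspring, making early stochastic loss
  # of the favourable allele rare.
  qtn <- purrr::map_dfr(seq_len(params$n_qtn), function(q) {
    c_i <- ((q - 1L) %% n_chrom) + 1L
    mid <- params$chrom_lengths[c_i] / 2
    pos_c <- pos_by_chrom[[c_i]]
    row <- which.min(abs(pos_c - mid))
    carrier_sire <- sample.int(params$founder_sires, 1)
    col <- 2L * (carrier_sire - 1L) + sample.int(2L, 1)
    newcol <- integer(ncol(fo$haps[[c_i]]))
    newcol[col] <- 1L
    fo$haps[[c_i]][row, ] <<- newcol
    tibble(chrom_index = c_i, chrom = paste0("chr", c_i),
           pos = pos_c[row], row = row,
           founder_freq = 1 / ncol(fo$haps[[c_i]]),
           effect = rep_len(params$qtn_effects, params$n_qtn)[q])
  })

  g0 <- genetic_values(fo$haps, qtn)
  vg <- var(g0) + params$polygenic_sd^2
  sigma_e <- if (vg > 0) sqrt(vg * (1 - params$heritability) / params$heritability) else 1

  n_need <- params$sires_per_generation + params$dams_per_generation
  n_off <- max(round(n_need / params$selected_fraction), 2L * n_need)
  if (round(params$selected_fraction * n_off) < params$sires_per_generation) {
    abort("selected_fraction too small to supply the required sires")
  }
  total_gen <- params$selection_generations + params$maintenance_generations

  n_founders <- length(fo$founder_line)
  poly0 <- rnorm(n_founders, 0, params$polygenic_sd)
  lines <- list(
    lineA = list(haps = fo$haps, poly = poly0, sires = which(fo$sex == "M"),
                 dams = which(fo$sex == "F"), direction = -1),
    lineB = list(haps = fo$haps, poly = poly0, sires = which(fo$sex == "M"),
                 dams = which(fo$sex == "F"), direction = 1))

  line_means <- list(); pedigree <- list()
  for (t_gen in seq_len(total_gen)) {
    selecting <- t_gen <= params$selection_generations
    for (ln in names(lines)) {
      st <- lines[[ln]]
      # matings: balanced parent usage (each sire/dam contributes equally
      # many candidates), which is how a closed line limits inbreeding
      sires <- rep_len(sample(st$sires), n_off)
      dams <- rep_len(sample(st$dams), n_off)
      off <- breed(st$haps, pos_by_chrom, sires, dams, params$recomb_rate)
      # infinitesimal polygenic background: midparent + Mendelian sampling
      poly <- (st$poly[sires] + st$poly[dams]) / 2 +
        rnorm(n_off, 0, params$polygenic_sd / sqrt(2))
      g <- genetic_values(off, qtn) + poly
      pheno <- g + rnorm(n_off, 0, sigma_e)
      sex <- sample(c("M", "F"), n_off, replace = TRUE)
      if (selecting) {
        ord <- order(st$direction * pheno, decreasing = TRUE)
        males <- ord[sex[ord] == "M"]
        females <- ord[sex[ord] == "F"]
        if (length(males) < params$sires_per_generation ||
            length(females) < params$dams_per_generation) {
          abort("not enough candidates of one sex; increase selected_fraction")
        }
        new_sires <- males[seq_len(params$sires_per_generation)]
        new_dams <- females[seq_len(params$dams_per_generation)]
      } else {
        # maintenance phase limits inbreeding: the new parents are spread
        # over as many sire families as possible (one male per family
        # first), which roughly doubles Ne relative to random choice
        new_sires <- balanced_pick(which(sex == "M"), sires,
                                   params$sires_per_generation)
        new_dams <- balanced_pick(which(sex == "F"), sires,
                                  params$dams_per_generation)
      }
      lines[[ln]] <- list(haps = off, poly = poly, sires = new_sires,
                          dams = new_dams, direction = st$direction)
      line_means[[length(line_means) + 1]] <-
        tibble(generation = t_gen, line = ln, mean_genetic = mean(g),
               mean_phenotype = mean(pheno))
      pedigree[[length(pedigree) + 1]] <-
        tibble(generation = t_gen, line = ln,
               n_sires = params$sires_per_generation,
               n_dams = params$dams_per_generation,
               n_candidates = n_off, selected = selecting)
    }
  }

  # final line frequencies at the QTNs (over each line's final cohort)
  qtn$freq_lineA <- vapply(seq_len(nrow(qtn)), function(i) {
    mean(hap_dosage_row(lines$lineA$haps, qtn$chrom_index[i], qtn$row[i])) / 2
  }, numeric(1))
  qtn$freq_lineB <- vapply(seq_len(nrow(qtn)), function(i) {
    mean(hap_dosage_row(lines$lineB$haps, qtn$chrom_index[i], qtn$row[i])) / 2
  }, numeric(1))

  # sequencing panel: birds from the final cohorts plus F1 crosses
  pick_a <- sample(c(lines$lineA$sires, lines$lineA$dams), params$n_sample_lineA)
  pick_b <- sample(c(lines$lineB$sires, lines$lineB$dams), params$n_sample_lineB)
  f1_sires <- sample(lines$lineB$sires, params$n_f1, replace = params$n_f1 > length(lines$lineB$sires))
  f1_dams <- sample(lines$lineA$dams, params$n_f1)
  f1_haps <- lapply(seq_len(n_chrom), function(c_i) {
    HB <- lines$lineB$haps[[c_i]]; HA <- lines$lineA$haps[[c_i]]
    pos <- pos_by_chrom[[c_i]]
    M <- matrix(0L, nrow(HB), 2L * params$n_f1)
    for (o in seq_len(params$n_f1)) {
      s <- f1_sires[o]; d <- f1_dams[o]
      M[, 2L * o - 1L] <- meiosis_gamete(HB[, 2L * s - 1L], HB[, 2L * s], pos,
                                         params$recomb_rate)
      M[, 2L * o] <- meiosis_gamete(HA[, 2L * d - 1L], HA[, 2L * d], pos,
                                    params$recomb_rate)
    }
    M
  })

  take <- function(haps, idx) {
    do.call(rbind, lapply(seq_along(idx), function(i) {
      unlist(lapply(haps, function(H) {
        H[, 2L * idx[i] - 1L] + H[, 2L * idx[i]]
      }))
    }))
  }
  dos <- rbind(take(lines$lineA$haps, pick_a),
               take(lines$lineB$haps, pick_b),
               take(f1_haps, seq_len(params$n_f1)))

  alleles <- with_rng(NULL, {
    pairs <- c("A", "C", "G", "T")
    ref <- sample(pairs, nrow(fo$snps), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(pairs, b), 1), character(1))
    list(ref = ref, alt = alt)
  })
  snps <- fo$snps |> mutate(ref = alleles$ref, alt = alleles$alt)
  samples <- tibble(
    id = c(paste0("LL", seq_len(params$n_sample_lineA)),
           paste0("FL", seq_len(params$n_sample_lineB)),
           paste0("F1_", seq_len(params$n_f1))),
    population = rep(c("lineA", "lineB", "F1"),
                     c(params$n_sample_lineA, params$n_sample_lineB,
                       params$n_f1)))
  genotypes <- geno_matrix(snps, samples, dos)

  list(genotypes = genotypes,
       truth = list(qtn = select(qtn, -"chrom_index", -"row"),
                    line_means = bind_rows(line_means),
                    pedigree = bind_rows(pedigree),
                    sigma_e = sigma_e))
}

# ---- companion fixtures ---------------------------------------------------

#' Generate companion fixtures around the simulated truth
#'
#' Produces the side inputs the downstream analyses consume: toy gene
#' models tiling each QTN neighbourhood (some spanning the QTN), QTL
#' intervals of +/- `qtl_halfwidth` around each QTN (mirroring the ~12 Mb
#' linkage intervals of the real design), a pyrosequencing-style ASE table
#' with a programmable allelic imbalance, and a qPCR Ct table with a line
#' effect on the target gene.
#'
#' @param truth `truth` element of [simulate_design()].
#' @param params The [design_params()] used.
#' @param imbalance_odds True cDNA allelic odds ratio (1 = balanced;
#'   default 0.6, the scale seen for a cis-regulated gene).
#' @param depth Pyrosequencing read depth per assay.
#' @param n_ase_individuals,ase_replicates ASE design.
#' @param ct_shift Target-gene Ct difference between lines (cycles).
#' @param ct_sd Within-line Ct standard deviation.
#' @param n_ct Individuals per line in the Ct table.
#' @param qtl_halfwidth Half-width of QTL intervals around QTNs (bp).
#' @param seed Seed (defaults to `params$seed + 1`).
#' @return List of tibbles: `genes`, `qtl`, `ase`, `ct`.
#' @export
make_fixtures <- function(truth, params, imbalance_odds = 0.6, depth = 500,
                          n_ase_individuals = 5L, ase_replicates = 2L,
                          ct_shift = 1.4, ct_sd = 0.4, n_ct = 12L,
                          qtl_halfwidth = 6e6, seed = params$seed + 1L) {
  with_rng(seed, {
    genes <- purrr::map_dfr(seq_len(nrow(truth$qtn)), function(i) {
      q <- truth$qtn[i, ]
      c_len <- params$chrom_lengths[match(q$chrom,
                                          paste0("chr", seq_along(params$chrom_lengths)))]
      starts <- seq(max(1, q$pos - 50000), min(c_len - 4000, q$pos + 50000),
                    by = 10000)
      tibble(gene_id = sprintf("G_%s_%d", q$chrom, seq_along(starts)),
             chrom = q$chrom, start = as.integer(starts),
             end = as.integer(starts + 4000),
             strand = rep_len(c("+", "-"), length(starts)))
    })
    qtl <- truth$qtn |>
      mutate(id = paste0("QTL_", .data$chrom),
             start = as.integer(pmax(1, .data$pos - qtl_halfwidth)),
             end = as.integer(pmin(
               params$chrom_lengths[match(.data$chrom,
                 paste0("chr", seq_along(params$chrom_lengths)))],
               .data$pos + qtl_halfwidth))) |>
      select("id", "chrom", "start", "end")
    p_cdna <- imbalance_odds / (1 + imbalance_odds)
    ase <- tidyr::expand_grid(individual = paste0("F1_", seq_len(n_ase_individuals)),
                              replicate = seq_len(ase_replicates)) |>
      mutate(gdna_ref = rbinom(n(), depth, 0.5) / depth,
             cdna_ref = rbinom(n(), depth, p_cdna) / depth)
    ct <- tibble(
      sample = c(paste0("FL", seq_len(n_ct)), paste0("LL", seq_len(n_ct))),
      line = rep(c("lineB", "lineA"), each = n_ct),
      ct_target = c(rnorm(n_ct, 23.5, ct_sd), rnorm(n_ct, 23.5 + ct_shift, ct_sd)),
      ct_reference = rnorm(2 * n_ct, 20, 0.15))
    list(genes = genes, qtl = qtl, ase = ase, ct = ct)
  })
}

#' Write fixtures to disk in their standard formats
#'
#' Gene models as GFF3, QTL as BED, ASE and Ct tables as TSV.
#'
#' @param fx List from [make_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gr <- GenomicRanges::GRanges(fx$genes$chrom,
                               IRanges::IRanges(fx$genes$start, fx$genes$end),
                               strand = fx$genes$strand)
  gr$type <- "gene"
  gr$ID <- fx$genes$gene_id
  paths <- c(genes = file.path(dir, "genes.gff3"),
             qtl = file.path(dir, "qtl.bed"),
             ase = file.path(dir, "ase.tsv"),
             ct = file.path(dir, "ct.tsv"))
  rtracklayer::export(gr, paths["genes"], format = "gff3")
  qgr <- intervals_to_gr(fx$qtl)
  qgr$name <- fx$qtl$id
  rtracklayer::export(qgr, paths["qtl"], format = "bed")
  write.table(fx$ase, paths["ase"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fx$ct, paths["ct"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
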