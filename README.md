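# hapsweep

Haplotype-based selective-sweep detection for divergently selected lines,
plus the downstream evidence chain that turns sweep regions into candidate
causal genes.

Two closed lines bred from one founder stock by selecting opposite
extremes of a quantitative trait differ everywhere by drift and locally by
selection. `hapsweep` finds the local signals with the hapFLK statistic — a
haplotype-cluster extension of the FLK differentiation test that corrects
for drift through a population kinship matrix — and connects them to
previously mapped QTL intervals, coding-consequence annotation, and
cis-regulation evidence (allele-specific expression in F1 crossbreds,
delta-Ct qPCR differential expression). A forward-in-time simulator of the
divergent breeding design (founder mix of six ancestral lines, truncation
selection, maintenance with few sires, crossbred F1 panel) makes the whole
pipeline testable end to end.

## The model in brief

* **Kinship**: Reynolds distance `D` between the lines from a sparse SNP
  subsample; with two lines, `F = diag(D/2, D/2)` (midpoint rooting); more
  lines use a midpoint-rooted neighbor-joining tree.
* **FLK** at one SNP: `T = (p − p̂0·1)' [p̂0(1−p̂0)F]⁻¹ (p − p̂0·1)` with
  `p̂0 = (1'F⁻¹p)/(1'F⁻¹1)`.
* **Haplotype clusters**: a fastPHASE-style HMM on unphased genotypes
  (hidden state = unordered cluster pair), `K = 6` clusters by default,
  fitted by exact Baum–Welch; F1 birds enter the fit but not the line
  frequencies.
* **hapFLK**: the FLK quadratic form on cluster frequencies with
  covariance `F ⊗ B0`, `B0 = diag(p̂0) − p̂0p̂0'`, pseudo-inverted;
  averaged over independent EM fits (label-invariant).
* **Significance**: a robust scaled chi-square null (`a·χ²_d` by
  median/MAD matching), Storey q-values, sweeps called at `q < 0.1` and
  merged within 50 kb.

## Worked example

```r
library(hapsweep)

# simulate the divergent-line design at desk scale: two 3-Mb chromosomes,
# one strongly selected locus, 7+4 line birds and 9 F1 sampled
params <- design_params(chrom_lengths = rep(3e6, 2), seed = 101)
sim <- simulate_design(params)
sim$genotypes
#> <geno_matrix> 20 individuals x 15544 SNPs
#>   populations: F1=9, lineA=7, lineB=4
#>   chromosomes: chr1, chr2
sim$truth$qtn
#> # A tibble: 1 x 6
#>   chrom     pos founder_freq effect freq_lineA freq_lineB
#>   <chr>   <int>        <dbl>  <dbl>      <dbl>      <dbl>
#> 1 chr1  1500018      0.00549      3          0          1

# MAF filter, kinship, haplotype-cluster scan, robust null, q-values
scan <- run_sweep_scan(sim$genotypes,
                       ccfg = cluster_config(n_fits = 5,
                                             em_iterations = 20, seed = 8))
scan
#> <hapflk_scan> 2968 SNPs, null ~ 0.273 * chisq(23.15), pi0 = 1.000
#>   0 SNP(s) with q < 0.1
glance(scan)
tidy(scan)          # chrom, pos, hapflk, p, q, significant
autoplot(scan)      # genome-scan plot

# the genome-wide maximum of the averaged statistic
tab <- tidy(scan)
tab[which.max(tab$hapflk), c("chrom", "pos")]
#>   chrom    pos
#> 1 chr1  906918     # on the swept chromosome, ~0.6 Mb from the QTN

# sweep regions, QTL colocalization, enrichment
sweeps <- call_sweeps(scan)
fx <- make_fixtures(sim$truth, params)
overlap_qtl(annotate_genes(sweeps, fx$genes), fx$qtl)
coverage_enrichment(sweeps, fx$qtl, sum(params$chrom_lengths))

# expression layer: allele-specific expression and delta-Ct comparison
ase_analysis(fx$ase)$test
#> # A tibble: 1 x 4
#>       n mean_ratio statistic       p
#> 1     5      0.558         0  0.0625
expr <- relative_expression(fx$ct$ct_target, fx$ct$ct_reference)
differential_expression(expr[fx$ct$line == "lineB"],
                        expr[fx$ct$line == "lineA"])
#> fold_change 2.29 at p = 1.5e-5 for the programmed 1.4-cycle shift
```

The mean allelic ratio of ~0.56 says the marked allele produces ~44% less
transcript than its partner (an exact signed-rank test at n = 5 cannot go
below p = 0.0625); the fold change of ~2.3 between lines is the sampled
realization of the 2^1.4 = 2.64 expectation for a 1.4-cycle Ct shift.

Under pure drift the scan reports zero significant SNPs (the robust null
absorbs the line divergence); with the selected locus present, the
genome-wide maximum of the averaged hapFLK lands on the swept chromosome,
typically within a megabase of the causal site — the frozen hitchhiked
block around a fixed allele is wide at these population sizes, so
region-level evidence (sweep calls, QTL overlap), not single-SNP argmax,
is the meaningful readout (see the methods vignette).

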