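---
title: "Detecting selective sweeps in divergently selected lines with hapsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps in divergently selected lines with hapsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hapsweep)
```

## The problem

Two closed lines bred from one founder stock by selecting opposite extremes
of a single quantitative trait accumulate two kinds of allele-frequency
differences: drift, everywhere, and selection, locally around the causal
loci. With whole-genome SNP data from a handful of birds per line, the task
is to find the local signals without being swamped by the drift — and then
to connect candidate regions to independent evidence: previously mapped QTL
intervals, coding-consequence annotation of the variants they contain, and
cis-regulation readouts (allele-specific expression in F1 crossbreds,
qPCR differential expression between the lines).

`hapsweep` implements that full chain, together with a forward-in-time
simulator of the breeding design so that every stage can be exercised and
calibrated without access to the original animals.

## The hapFLK model

The scan statistic extends the single-SNP FLK test to haplotypes.

**Kinship.** Drift makes allele frequencies in population $j$ wander around
the ancestral frequency $p_0$ with variance approximately
$F_{jj}\,p_0(1-p_0)$, where $F$ is the drift covariance ("kinship") matrix
of the populations. $F$ is estimated from the genome-wide Reynolds
distance
$$D = \frac{\sum_s (p_{1s}-p_{2s})^2}{\sum_s\left(1 - p_{1s}p_{2s} - (1-p_{1s})(1-p_{2s})\right)},$$
computed on a sparse SNP subsample (1% by default — kinship needs few
SNPs). With two populations and no outgroup the single tree edge is rooted
at its midpoint, $F = \mathrm{diag}(D/2,\,D/2)$; with more populations a
neighbor-joining tree is fitted and midpoint-rooted, and $F$ collects
shared root-to-ancestor branch lengths. The midpoint choice is symmetric
and is the only defensible rooting without an outgroup; the split is
configurable for sensitivity analysis.

**Single-SNP FLK.** With $\hat p_0 = (1'F^{-1}p)/(1'F^{-1}1)$ (the GLS
root estimate),
$$T_{FLK} = (p - \hat p_0 1)'\,[\hat p_0(1-\hat p_0)F]^{-1}\,(p - \hat p_0 1),$$
which under neutrality is approximately $\chi^2$ with $J-1$ degrees of
freedom for $J$ populations.

**Haplotype clusters.** Single SNPs waste the linkage information of dense
data. Following the fastPHASE model, each chromosome is a mosaic of $K$
latent haplotype clusters; at SNP $s$ cluster $k$ emits the alternate
allele with probability $\theta_{ks}$, cluster weights are
$\alpha_{\cdot s}$, and between adjacent SNPs a chromosome switches
cluster with probability $r_s$, landing on $k$ with probability
$\alpha_{ks}$. Genotypes are unphased, so the hidden state is the
*unordered pair* of clusters carried by the two chromosomes; the forward–
backward recursions run over the $K^2$ ordered pairs with $O(K^2)$ work
per SNP thanks to the rank-one structure of the transition kernel, in
scaled probability space. All Baum–Welch updates (emission counts,
occupancies, jump counts) use exact expected sufficient statistics, so the
training log-likelihood is non-decreasing — a property the tests assert.

`K = 6` by default, matching the six ancestral lines mixed in the founder
stock of the design the package emulates. Crossbred F1 birds are included
in the EM (they carry one chromosome from each line, enlarging the sample
to 20 birds) but are excluded from line cluster frequencies and kinship.

**hapFLK.** With per-line cluster frequency vectors $p_j$ (on the
$K$-simplex), the root frequencies $\hat p_{0k}$ are estimated per cluster
by the FLK root estimator and renormalized; writing
$B_0 = \mathrm{diag}(\hat p_0) - \hat p_0\hat p_0'$,
$$\mathrm{hapFLK} = (p - 1\otimes \hat p_0)'\,(F\otimes B_0)^{+}\,(p - 1\otimes \hat p_0).$$
$B_0$ is singular (frequencies sum to one), hence the pseudo-inverse. On
the sum-zero space where the deviations live, $\mathrm{diag}(1/\hat
p_{0k})$ is an exact generalized inverse of $B_0$, which the implementation
uses; the eigendecomposition-based pseudo-inverse serves as an independent
oracle in the test suite. The statistic is invariant to cluster
relabeling, so the EM fits need no label alignment: the package runs
`n_fits` independent fits (default 10) and averages the *statistic*.

**Significance.** EM noise and the small sample sizes make the theoretical
null unusable; instead the genome-wide empirical distribution is modelled
as $a\,\chi^2_d$ with $(a, d)$ estimated by matching the sample median and
MAD to their $\chi^2$ counterparts. Median and MAD ignore the extreme
tails, so the handful of truly selected loci — outliers by construction —
are automatically down-weighted. (A trimmed maximum-likelihood variant is
available behind `scan_config(null_method = "trimmed_ml")`.) Upper-tail
p-values follow, then Storey q-values with
$\hat\pi_0 = \min(1, \#\{p > \lambda\}/((1-\lambda)m))$, $\lambda = 0.5$.
SNPs with $q < 0.1$ are called under selection: 10% of the called SNPs are
expected false positives.

**Regions.** Consecutive significant SNPs at most `merge_gap` apart
(default 50 kb — half the expected sweep size of this design, see below)
merge into one sweep region; regions need at least two significant SNPs
(the published summary's minimum SNPs-per-sweep is 2); boundaries are the
outermost significant SNPs. Regions are summarized per chromosome, with
the overall mean sweep size and SNPs/sweep reported both as unweighted
means of the per-chromosome means (the convention that reproduces the
published overall row) and as sweep-count-weighted means. Sweep/QTL
colocalization is inclusive-interval intersection, and coverage enrichment
uses a Pearson $\chi^2$ on the 2×2 table of base-pair counts
{sweep, non-sweep} × {QTL, non-QTL}. The analytic expectation for the
sweep extent after $T$ generations in a haploid sample of size $n$ with
recombination rate $\rho$/bp is $1/(n\rho T)$ — about 95 kb for
$n = 10$, $\rho = 3\times10^{-8}$, $T = 35$.

## Consequence annotation and the expression layer

The annotator classifies SNPs against transcript models: essential splice
region (the two intronic bases flanking each exon), codon-level classes
inside the CDS (standard genetic code, strand-aware, frame from the CDS),
UTR, intronic, intergenic; a SNP hitting several transcripts keeps the
most severe class. It deliberately covers only the classes the pipeline
reports — it is not a re-implementation of a full effect-predictor
ontology, and regulatory-region classes (which require
annotation-distance conventions that are not part of this package's
scope) are not produced.

The expression layer implements the ΔCt arithmetic
($\mathrm{expr} = 2^{-(Ct_{target}-Ct_{ref})}$, Student t between groups,
fold change as ratio of means), tissue profiling (samples with
$Ct > 30$ excluded; fold change relative to the weakest retained tissue),
and allele-specific expression: pyrosequencing reference-allele
frequencies in cDNA are turned into odds, divided by the gDNA odds of the
same heterozygote (cancelling assay skew — gDNA is balanced in truth),
giving an allelic ratio whose departure from 1 is tested by a one-sample
Wilcoxon signed-rank on log ratios. The named "Mann–Whitney against 1" of
qPCR practice is degenerate as a two-sample test; the signed-rank form is
its standard realization, and a two-sample mode (cDNA vs gDNA odds) is
available via `ase_analysis(pool_replicates = TRUE)` plus a manual
`wilcox.test` if wanted. The exact null distribution is computed by a
sign-flip generating-function dynamic programme with midranks, so fully
tied ratio sets still receive their exact $2/2^n$ — `stats::wilcox.test`
falls back to a normal approximation there. Technical duplicates are
averaged within individual before testing (n = individuals); homozygous
individuals carry no allelic signal and are dropped.

## The synthetic breeding design

`design_params()` encodes the study conditions: a founder stock of 23
sires and 68 dams mixing six ancestral lines, seven generations of
divergent truncation selection on an additive fatness-like trait, 28
further generations of maintenance with 20 sires and 60 dams per line,
SNP density 2.6/kb, recombination $3\times10^{-8}$/bp/generation, and a
sequencing panel of 7 + 4 line birds and 9 F1.

Choices the design left open, fixed once here:

* **Founder haplotype structure.** Each ancestral line has a
  Balding–Nichols frequency profile ($F = 0.2$) around a shared ancestral
  frequency; the line contributes a consensus haplotype plus 12 prototypes
  deviating from it by 2% per SNP, and each founder chromosome is a mosaic
  of its line's prototypes (switch rate $2\times10^{-5}$/bp) with 1%
  residual flips. Lines are therefore internally cohesive relative to the
  between-line divergence — the premise behind using $K = 6$ clusters.
  Founder linkage disequilibrium comes from this mosaic construction, not
  from a coalescent simulation, keeping runtimes at desk scale.
* **The selected locus.** The QTN is a new mutation carried by a single
  founder-sire haplotype near the chromosome midpoint. A hard sweep from
  one haplotype background is the regime in which a haplotype-based scan
  has something to find; an allele starting from standing variation at
  intermediate frequency rises on many backgrounds and leaves almost no
  local footprint above the drift of a small-Ne design. A founder *sire*
  carries the copy because sires father many offspring, making early
  stochastic loss rare.
* **Trait architecture.** The trait is the QTN effect (default 3, in
  units of the polygenic standard deviation) plus an infinitesimal
  polygenic background (midparent + Mendelian sampling) and environmental
  noise scaled to heritability 0.5. The polygenic background matters: a
  monogenic trait makes truncation selection deterministic on the carrier
  family and collapses each line onto a single sire line genome-wide.
* **Mating.** Selection generations use strict truncation on phenotype
  (low tail in line A, high tail in line B) with balanced parent usage;
  maintenance generations spread the new parents over as many sire
  families as possible — the standard way a closed line limits inbreeding
  — which roughly doubles Ne relative to random parent choice.
* **Candidates.** `selected_fraction = 0.25`: each generation produces
  four candidates per retained parent slot, a typical poultry selection
  intensity.

Companion fixture generators (`make_fixtures()`) produce toy gene models
tiling each QTN neighbourhood, QTL intervals of ±6 Mb around each QTN
(mirroring the ~12 Mb linkage-mapping intervals of such designs),
pyrosequencing tables with a programmable allelic imbalance (default odds
0.6 at depth 500, the scale observed for a cis-regulated gene), and Ct
tables with a line shift (default 1.4 cycles, s.d. 0.4, n = 12 per line).

### What the simulator does and does not emulate

It reproduces the pedigree structure, selection regime, hard-sweep
hitchhiking, Mendelian inheritance with Poisson crossovers, and realistic
SNP density. It does not model mutation after the founder generation,
coalescent-exact ancestral variation, sex chromosomes, genotyping error,
or sequencing reads. Passing tests therefore demonstrate that the
statistics behave correctly under the design's drift and selection
process — not that the pipeline is robust to alignment or calling
artefacts of real data.

## Numerical choices

* Emission probabilities are floored at $10^{-3}$; cluster weights at
  $10^{-6}$ (renormalized); both prevent degenerate forward passes.
* Forward–backward runs in scaled probability space (per-SNP
  normalization), not log space, so likelihood accumulation is exact.
* The pseudo-inverse tolerance for $B_0$ treats singular values below
  $10^{-10}$ of the maximum as zero (oracle path); the production path
  uses the closed-form g-inverse, with zero-mass clusters contributing
  nothing.
* `fit_null` solves the median/MAD matching by one-dimensional root
  finding in $d$ over $[0.05, 500]$ on the log scale; the $\chi^2$ MAD is
  itself solved numerically.
* SNPs whose estimated root frequency sits at 0 or 1 are excluded from
  the FLK scan with a reported count rather than scored 0.
* Positions are 1-based inclusive internally; BED input/output converts
  at the boundary.

## Problem sizes

The default simulated genome is 5 chromosomes × 10 Mb (≈130k SNPs at
2.6/kb). The test-suite and acceptance-script simulations use 1–2
chromosomes of 2–6 Mb, 3–10 EM fits and 15–25 EM iterations; these sizes
were chosen as the package's desk-scale working points, and all
calibration and power statements in the tests are made at those sizes.
The scan cost is dominated by the EM core (compiled; about
$O(K^2 S N)$ per iteration), so runtime scales linearly in SNPs,
individuals, fits and iterations.

## Known limitations

* With two populations and very small panels the hapFLK statistic has an
  algebraic ceiling $4/(F_{11}+F_{22})$, reached wherever the two line
  samples share no haplotype cluster at all; under extreme drift the
  ceiling compresses the extreme tail of the scan. The empirical null
  absorbs the scale, but resolution inside saturated stretches is limited.
* **Localization resolution.** In a closed line with no post-founder
  mutation, hitchhiking erosion stops the moment the favourable allele
  fixes: the swept haplotype block freezes at whatever width survived at
  fixation. An allele strong enough to sweep reliably within the seven
  selection generations therefore leaves a fixed block of hundreds of
  kilobases to megabases — substantially wider than the classic
  $1/(n\rho T)$ expectation, which presumes erosion continuing over all
  $T$ generations. Combined with the statistic's ceiling over the frozen
  block, the genome-wide *argmax* of the averaged statistic identifies the
  sweep chromosome in ~90% of simulated replicates and lands within about
  a megabase in ~75%, but localizes to within 250 kb of the causal site in
  only ~15–35%. Region-level evidence (the sweep call, its overlap with a
  QTL interval) is the reliable readout at these sample sizes; single-SNP
  argmax distance is not.
* The median/MAD null is a surrogate for the original robust-estimation
  procedure, which is not specified in formulas anywhere; it is validated
  by recovery and calibration simulations rather than by matching any
  published sweep count.
* The annotator handles SNPs only (no indel consequences) and assumes
  transcript models with in-frame CDS.
* Reynolds distances on very few SNPs are noisy; the default 1% kinship
  subsample assumes a genome of at least a few hundred kilobases.
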