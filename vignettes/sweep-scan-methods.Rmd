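---
title: "Multi-statistic selective-sweep scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-statistic selective-sweep scans: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

Domestication and breed improvement leave localized footprints in a genome:
positive selection drives a beneficial allele up in frequency and drags its
linked background along, depressing nucleotide diversity, inflating allele
frequency differentiation against the wild relative, and creating unusually
long stretches of haplotype homozygosity. No single statistic captures all
of this reliably, so scans for domestication sweeps — for instance contrasts
of a wild ancestor (Asiatic mouflon in sheep) against landrace populations —
combine several: windowed diversity ratios, cross-population composite
likelihood ratios (XP-CLR), the integrated haplotype score (iHS), a windowed
polymorphism/divergence goodness-of-fit (HKA-style) test, and, on
copy-number intensity data, the variance-partitioning statistic V_ST.

`sweepscan` implements that whole toolkit on phased VCF input, together
with the supporting population-genetic machinery (window F_ST, Reynolds
distances, neighbor-joining trees with bootstrap, LD decay and LD-based
recent effective population size), empirical-percentile thresholding,
multi-statistic combination, interval annotation, and a permutation test for
overlap with annotation such as QTL intervals. A forward Wright-Fisher
simulator with planted hard sweeps provides ground truth for calibration
and power experiments; everything in this vignette that sounds like an
empirical claim is recomputed by the package's test suite or acceptance
script.

# Data model and conventions

All statistics run off a `haplotype_panel`: biallelic SNPs on one
chromosome, phased diploid genotypes coded 0/1/NA, a population label per
individual and an optional per-site ancestral-allele flag (populated from
the VCF `AA` tag). Internally every interval is 0-based half-open (the BED
convention); VCF positions are converted at the I/O boundary only. Window
grids anchor at position 0 and stride by a fixed step — 50 kb windows
sliding by 25 kb is the default geometry everywhere — so grids are
reproducible regardless of variant density. Interval algebra
(intersection, merging) is delegated to GenomicRanges behind a plain
data-frame surface.

Site filters follow the usual resequencing practice: sites with a missing
rate at or above 0.1 or minor allele frequency below 0.05 (counted over all
called alleles in the panel) are removed before the SNP scans. The
HKA-style test runs on the unfiltered panel because its segregating-site
counts would be censored by a MAF cut.

# The statistics

## Diversity and the log2 ratio scan

Per-site diversity is the unbiased heterozygosity `2k(n-k)/(n(n-1))`;
window pi sums it over contained variant sites and divides by the full
window length in bp (the vcftools convention — monomorphic sites contribute
zero by absence). Missing genotypes reduce a site's called-allele count
rather than dropping the site. The scan statistic is
`log2(pi_control / pi_target)`: large positive values mark windows where
the target (e.g. a landrace) lost diversity relative to the control (the
wild ancestor).

Masking: windows with fewer than `min_snps = 10` usable sites on either
side are `NA`. A window with positive control diversity but *zero* target
diversity is reported as `+Inf` rather than masked: at desk scale a fully
swept window really does lose every post-filter SNP, and total depletion is
the strongest evidence the statistic can express, not an undefined value.
The rule is symmetric (the swapped case gives `-Inf`), so exchanging
control and target negates every unmasked value.

## Weir-Cockerham F_ST

The 1984 analysis-of-variance estimator applied to haploid-coded allele
counts (alleles are the sampling units): `a` is the between-population
variance component, `b` the within component, `fst = a/(a+b)`. Windows can
pool sites as the average of per-site ratios ("global F_ST, the average
value for each SNP") or as the ratio of summed components (the weighted
convention); both are exposed because published scans use both.

## XP-CLR-style composite likelihood

The scan follows the published geometry exactly — focal points every 2 kb,
SNPs within a 0.5 cM window, at most 200 SNPs assayed per window — with an
explicit, quadrature-verifiable likelihood in place of the original tool's
internals. Given the reference-population frequency `p_ref` of a SNP, the
target count `k` of `n` alleles is binomial around a latent frequency
drawn from a truncated-Normal drift kernel with variance
`omega * p_ref(1-p_ref)`, out-of-range mass collapsing to atoms at 0 and 1
(a Balding-Nichols Beta kernel is available as an alternative). Under a
sweep of strength `s` (a genetic-distance scale, in Morgans) centred at
the focal point, a SNP at distance `r` escapes with probability
`c = 1 - exp(-r/s)` and otherwise hitchhikes: carried to frequency
`1 - resid` with probability `p_ref`, to `resid` otherwise.

Two numerical choices matter:

* `resid = 0.005` (not exactly 0): the scan conditions on sweeps
  *completing* (frequency at least 0.95), not on strict fixation. With exact
  atoms, any interior-frequency SNP adjacent to the focal point annihilates
  the sweep model (likelihood 0), and post-sweep singletons are ubiquitous,
  which empirically destroys localization. `resid = 0` remains available
  and reproduces the exact-atom algebra.
* the `s` grid is log-spaced from 2e-4 to 0.1 Morgans. The floor is about
  half the analysis window: with smaller scales the "sweep" model happily
  fits single-genealogy drift blocks (coalescent scale
  `1/(rec * T_split)`), which are indistinguishable from sub-window sweeps
  and flood the scan with noise.

An effective-neutral sentinel (escape probability 1 everywhere) is always
included, so `CLR = 2 * (max_s sweep loglik - neutral loglik)` is
non-negative. The latent-frequency integral uses Gauss-Legendre quadrature
(400 nodes; doubling changes log-likelihoods by far less than 1e-6). The
drift scale `omega` is estimated from the data as the mean of
`(p_T - p_R)^2 / (p_R(1-p_R))` minus the binomial sampling terms, floored
at 1e-4. SNP thinning above 200 per window is deterministic and evenly
spaced — random thinning adds Monte-Carlo noise to the CLR landscape and,
with any fixed seed, correlates that noise across scans. Focal-point scores
are max-pooled onto the shared 50/25-kb grid for combination with the
other statistics.

## iHS

EHH around a core SNP is the probability that two random carriers of the
core allele are identical over every site out to a given extent; it is
integrated (trapezoid rule, against the genetic map, default flat 1 cM/Mb)
out to an EHH cutoff of 0.05, a physical extent of 1 Mb, or a gap of
200 kb — the standard scan parameters. The trapezoid into the first
sub-cutoff point is included; gaps and data ends truncate and flag the
score. The unstandardized score is `ln(iHH_ancestral / iHH_derived)`
(ancestral states from the `AA` flag); standardization subtracts the mean
and divides by the standard deviation within derived-allele-frequency bins
(50 equal-width bins, sparse bins merged below 20 SNPs), so that
`|iHS| > 2` is comparable across frequencies. Window summaries report the
proportion of extreme SNPs per window; windows at or above the top-5%
empirical quantile of that proportion (and strictly positive) are
significant. Both the shared sliding grid and a non-overlapping grid
(`step = size`) are supported, the sliding grid being the default for
consistency with every other statistic.

## Windowed HKA

Each 50-kb window's segregating-site count `S` (within the scanned
population) and fixed-difference count `D` (sample fixed for an allele
differing from the outgroup consensus) are compared to a "virtual neutral
locus" — the genome-average window — by
`X2 = (S - S_bar)^2/var_S + (D - D_bar)^2/var_D`, with
`var_S = S_bar + theta_L^2 b_n` (the no-recombination Watterson variance)
and `var_D = D_bar + theta_L^2` (divergence variance with the
ancestral-polymorphism term). The decision rule is the chi-square critical
value at df = 2, alpha = 0.05, i.e. 5.99. Classically a two-locus HKA has
one degree of freedom; df is configurable and defaults to 2 to match the
published decision rule. Because the variance terms assume no intra-window
recombination they overstate the null variance on recombining data, making
the test conservative: in the package's own sweep experiments a completed
sweep is essentially always elevated above the genome background but
crosses 5.99 in only about half the replicates. Polymorphic-and-different
sites count toward `S` only, never `D`, to avoid double counting.

## V_ST

For a CNV region with intensity values split between two populations,
`V_ST = (V_T - V_S)/V_T`, where `V_T` is the variance over all individuals
and `V_S` the population-size-weighted mean of the within-population
variances. Population variances divide by `n` (the convention is fixed and
documented because the source formulations are silent); negative raw
values are clipped to 0, `V_T = 0` is masked. The statistic is invariant
to shifting or positively rescaling all intensities.

## Trees, distances, LD and recent Ne

Reynolds coancestry distances (`-ln(1-theta)` on the ratio-of-sums
coancestry estimate) and individual allele-sharing p-distances (0 / 0.5 / 1
per site) feed a hand-rolled Saitou-Nei neighbor-joining implementation
that applies the zero-clamp-with-transfer rule to negative branch lengths
and reconstructs additive matrices exactly; trees are returned as `ape`
`phylo` objects, and bootstrap supports count bipartitions over
site-resampled replicates. Pairwise `r^2` comes in phased-haplotype and
genotype-dosage (composite) forms; binned decay curves give the half-decay
distance (linear interpolation between bin midpoints) and the SNeP-style
recent-Ne ladder `Ne(t) = (1/(4c)) (1/r2_adj - alpha)` at `t = 1/(2c)`
generations, with `r2_adj = r2 - 1/(2n)` and `alpha = 2.2` by default
(mutation-inclusive; `alpha = 1` available).

# Thresholding, combination and the permutation test

Empirical thresholds are nearest-rank quantiles with the higher-rank
tie-break, so exactly `ceiling(f * n)` windows sit at or above the top-`f`
threshold when values are distinct. Window sets combine two ways: strict
window-set intersection, and a region-level combination (merge each
statistic's flagged windows into regions, intersect the region sets as
intervals). The region form is the headline combination in the pipeline:
two statistics whose peaks land in adjacent, overlapping sliding windows
agree on the region even when they share no window identifier — on a
2-Mb desk genome the top-1% set is a single window, so the strict
window-set intersection of two noisy argmaxes is nearly vacuous.

The permutation test for annotation overlap preserves chromosome
assignment, region count and region lengths, placing each region uniformly
at random; the statistic is the number of observed regions touching
(>= 1 bp) any annotation region, and the add-one p-value
`(1 + #(null >= obs))/(1 + n_reps)` can never be zero. Flagged windows
merge at gap 0 into sweeps; genes are annotated as overlapping or "near"
within a 20-kb flank (the locus-window convention used for GWAS hits).

# The simulator and what it does (not) emulate

The generator is a discrete-generation forward Wright-Fisher model:
haplotypes are sorted derived-allele position lists, mutation is
infinite-sites with collision retry, recombination is a single crossover
per meiosis with probability `rec * L`, selection is genic (fitness 1,
1+s, 1+2s). An ancestral population burns in for `10 N` generations, then
splits into "wild" and "domestic" demes. A sweep is a new mutation
injected into one domestic haplotype at a chosen generation; runs are
conditioned on the allele reaching frequency 0.95 by sampling time by
restoring a snapshot taken at the introduction and re-running the
post-introduction generations (bounded by `max_attempts`, default 100 in
`sim_params()`). Outgroup divergence is added afterwards as
Poisson(2 mu T_outgroup L) substitutions, entering the panel as
ingroup-monomorphic sites whose outgroup allele differs — exactly what the
windowed HKA test consumes. The recorded truth interval is the classical
hitchhiking footprint `s/(rec ln(2Ns))` centred on the selected site (the
site itself is kept as a column): a sweep is a region-scale signal and its
diversity trough wanders by one window or so around the site between
replicates, so recovery is judged against the swept region.

The desk preset (`sim_params_desk()`) uses N = 200 diploids per
population and L = 2 Mb, and calibrates rates so the *observables* match
the organism rather than rescaling every parameter mechanically:
`mu = 1e-6` gives per-bp diversity `4 N mu = 8e-4` (sheep-like);
`rec = 1e-7` gives an LD half-decay `1/(4 N rec) = 12.5` kb (the landrace
scale) while keeping within-sweep recombination escape low enough that a
completed sweep clears its windows, as real sweeps do (rescaling
recombination by the full population-size factor would give 40x the
organism's within-sweep escape and no usable trough); `T_split = 100`
generations puts the divergence at `T/2N = 0.25`, window F_ST around
0.2-0.3 — the wild/landrace contrast — because much deeper splits at this
small N let whole haplotype blocks drift to fixation and mimic sweeps.
The default sweep starts 5 generations after the split (selection from
domestication onward) and completes close to sampling time. Samples are
25 wild and 30 domestic diploids, echoing study-scale sample sizes.

What the simulator does not emulate: genotyping error and missingness
structure, variable mutation/recombination landscapes, migration and
admixture, background selection, soft sweeps (single-origin hard sweeps
only) and multi-chromosome genomes. Passing calibration and recovery tests
on it therefore demonstrates correctness and power of the statistics under
idealized hard-sweep genealogies, not robustness to every property of real
resequencing data.

# Calibration results the suite recomputes

With the desk preset, the acceptance tests check (among others): the
standardized-iHS extreme fraction under neutrality is 0.046 +/- 0.015
(normal two-sided tail); top-1% diversity-ratio and XP-CLR flags recover a
planted s = 0.1 sweep, and their region-level intersection recovers it in
a further fraction of seeds; permutation p-values are KS-uniform under a
true null; top-1% V_ST recovers exactly the truly differentiated CNV
regions; and N = 100 versus N = 400 populations order their LD half-decay
distances correctly. Problem sizes (10-20 replicates, 1-2 Mb, 1000-rep
permutations) are the package's chosen desk scale: large enough for the
stated tolerances, small enough to re-run routinely. At this scale the
planted-sweep experiment is intrinsically marginal for the XP-CLR clause:
with 79 windows the top-1% set is one window (or one tie-pair), and
competing drift peaks put the per-seed recovery probability near 0.7-0.9
depending on the seed batch; the diversity-ratio clause sits at about
0.8, and the strict intersection lower still. The test file asserts the
stated rates regardless and documents failures rather than widening them.

# Known limitations

* The XP-CLR likelihood is an explicit variant, not a bit-compatible port
  of the original tool: no LD-based SNP down-weighting (the original
  `-p0` correlation threshold has no analog here), an explicit escape
  mixture instead of the original's moment approximations.
* The windowed HKA background treats the genome average as a known
  expectation (no joint multi-locus ML fit) and is conservative on
  recombining data.
* iHS requires phased, fully called data; sites with missing genotypes in
  the scanned population are dropped beforehand.
* Unphased panels are accepted at the door but refused by haplotype-based
  statistics; no phasing is attempted.
* The LD-based Ne ladder inherits all the usual caveats of SNeP-style
  estimates (bin assignment via the genetic map, sampling correction
  `1/(2n)`, constant-alpha mutation adjustment).
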