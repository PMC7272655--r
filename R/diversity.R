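# Nucleotide diversity, Watterson's theta, the folded site-frequency
# spectrum, and the log2 diversity-ratio scan.

#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity `2 k (n - k) / (n (n - 1))` for a
#' derived-allele count `k` out of `n` called alleles — the average number
#' of pairwise differences at one site.
#'
#' @param derived_count Derived (or alt) allele count(s) `k`.
#' @param total_called Called allele count(s) `n` (>= 2).
#' @return Per-site diversity in `[0, 1]`.
#' @export
site_pi <- function(derived_count, total_called) {
  if (any(total_called < 2))
    stop("site_pi needs at least 2 called alleles")
  stopifnot(all(derived_count >= 0), all(derived_count <= total_called))
  2 * derived_count * (total_called - derived_count) /
    (total_called * (total_called - 1))
}

#' Watterson's theta per bp
#'
#' `S / (a_n L)` with `a_n` the harmonic number of `n - 1`.
#'
#' @param segregating_sites Count of segregating sites `S`.
#' @param n_haplotypes Sample size in haplotypes (>= 2).
#' @param length Sequence length in bp.
#' @return Per-bp theta_W.
#' @export
watterson_theta <- function(segregating_sites, n_haplotypes, length) {
  stopifnot(n_haplotypes >= 2, length > 0)
  a_n <- sum(1 / seq_len(n_haplotypes - 1))
  segregating_sites / (a_n * length)
}

#' Windowed nucleotide diversity and Watterson's theta
#'
#' Per window, the sum of per-site diversity over contained variant sites
#' divided by the full window length in bp (monomorphic sites contribute 0
#' by absence) — the windowed-pi convention of vcftools. Missing genotypes
#' reduce a site's called-allele count rather than dropping the site.
#'
#' @param panel A [haplotype_panel()].
#' @param grid A [make_windows()] grid.
#' @param population Population label to compute within.
#' @return The grid with columns `n_snps` (sites with >= 2 called alleles in
#'   the window), `pi` and `theta_w` (both per bp).
#' @export
window_pi <- function(panel, grid, population) {
  ac <- allele_counts(panel, population)
  usable <- ac$n >= 2
  pos0 <- panel$pos - 1
  pi_site <- numeric(n_sites(panel))
  pi_site[usable] <- site_pi(ac$k[usable], ac$n[usable])
  seg <- as.numeric(usable & ac$k > 0 & ac$k < ac$n)
  len <- grid$end - grid$start
  out <- grid
  out$n_snps <- window_sum(as.numeric(usable), pos0, grid)
  out$pi <- window_sum(pi_site, pos0, grid) / len
  n_hap <- max(ac$n)
  out$theta_w <- if (n_hap >= 2) {
    s_win <- window_sum(seg, pos0, grid)
    s_win / (sum(1 / seq_len(n_hap - 1)) * len)
  } else NA_real_
  out
}

#' Folded site-frequency spectrum from genotype counts
#'
#' Histogram of minor-allele counts over classes `1 .. floor(n/2)`,
#' computed from called genotypes (Hardy-Weinberg phasing is irrelevant for
#' counts). Sites with missing data are either dropped (`on_missing =
#' "drop"`, keeping only sites fully called at `n` alleles) or down-projected
#' to `n_project` alleles by the hypergeometric expectation
#' (`on_missing = "project"`), accumulating fractional counts.
#'
#' @param panel A [haplotype_panel()].
#' @param population Population label.
#' @param n_project Target allele count for projection; default = the
#'   maximum fully-called count.
#' @param on_missing `"drop"` or `"project"`.
#' @return Named numeric vector of class counts; the sum equals the number
#'   of polymorphic sites retained.
#' @export
folded_sfs <- function(panel, population, n_project = NULL,
                       on_missing = c("drop", "project")) {
  on_missing <- match.arg(on_missing)
  ac <- allele_counts(panel, population)
  if (is.null(n_project)) n_project <- max(ac$n)
  stopifnot(n_project >= 2)
  classes <- seq_len(floor(n_project / 2))
  sfs <- stats::setNames(numeric(length(classes)), classes)
  if (on_missing == "drop") {
    keep <- ac$n == n_project & ac$k > 0 & ac$k < ac$n
    m <- pmin(ac$k[keep], ac$n[keep] - ac$k[keep])
    m <- m[m >= 1]
    tab <- table(factor(m, levels = classes))
    sfs <- sfs + as.numeric(tab)
  } else {
    keep <- which(ac$n >= n_project & ac$k > 0 & ac$k < ac$n)
    for (i in keep) {
      # hypergeometric expectation of drawing j derived among n_project
      j <- 0:n_project
      w <- stats::dhyper(j, ac$k[i], ac$n[i] - ac$k[i], n_project)
      m <- pmin(j, n_project - j)
      for (cl in classes)
        sfs[cl] <- sfs[cl] + sum(w[m == cl])
    }
  }
  sfs
}

#' Log2 diversity-ratio scan
#'
#' Per window, `ln(pi_control / pi_target) / ln(2)`: large positive values
#' mark windows where the target population (e.g. a landrace) has lost
#' diversity relative to the control (e.g. the wild ancestor). Windows where
#' either side has fewer than `min_snps` usable sites, or where both
#' diversities are zero, are masked (`NA`). A window with positive control
#' diversity but zero target diversity is total depletion — the most extreme
#' evidence the statistic can give — and is reported as `+Inf` (and `-Inf`
#' for the swapped case), so the mask rule stays symmetric and swapping
#' control and target negates every unmasked value.
#'
#' @param control,target Window tables from [window_pi()] on the same grid.
#' @param min_snps Minimum usable sites per window on each side.
#' @return The grid with a `pi_ratio_log2` column.
#' @export
pi_ratio_log2 <- function(control, target, min_snps = 10) {
  stopifnot(min_snps >= 1)
  if (!same_grid(control, target))
    stop("control and target must be on the same window grid")
  masked <- control$n_snps < min_snps | target$n_snps < min_snps |
    (control$pi == 0 & target$pi == 0)
  out <- control[c("chrom", "start", "end")]
  out$pi_ratio_log2 <- ifelse(masked, NA_real_,
                              log(control$pi / target$pi) / log(2))
  class(out) <- class(control)
  out
}
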