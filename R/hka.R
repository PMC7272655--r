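# Windowed polymorphism/divergence goodness-of-fit (HKA-style): each 50-kb
# window's segregating-site count S and fixed-difference count D against an
# outgroup are compared to a genome-average "virtual neutral locus" by a
# chi-square statistic with two standardized deviation terms.

#' Per-window polymorphism and divergence counts
#'
#' `S` counts sites polymorphic within the population sample; `D` counts
#' sites where the sample is fixed for an allele that differs from the
#' outgroup allele. Sites without an outgroup call are excluded from both
#' counts; polymorphic-and-different sites count toward `S` only.
#'
#' @param panel A [haplotype_panel()].
#' @param outgroup Integer per site: 0 = outgroup carries ref, 1 = alt,
#'   `NA` = no outgroup call.
#' @param grid A [make_windows()] grid.
#' @param population Population label.
#' @return Grid with columns `S` and `D`.
#' @export
hka_window_counts <- function(panel, outgroup, grid, population) {
  stopifnot(length(outgroup) == n_sites(panel))
  ac <- allele_counts(panel, population)
  usable <- ac$n >= 2 & !is.na(outgroup)
  poly <- usable & ac$k > 0 & ac$k < ac$n
  fixed_allele <- ifelse(ac$k == 0, 0L, ifelse(ac$k == ac$n, 1L, NA_integer_))
  fixdiff <- usable & !is.na(fixed_allele) & fixed_allele != outgroup
  pos0 <- panel$pos - 1
  out <- grid
  out$S <- window_sum(as.numeric(poly), pos0, grid)
  out$D <- window_sum(as.numeric(fixdiff), pos0, grid)
  out
}

#' Genome-average neutral background for the windowed HKA test
#'
#' The "virtual neutral locus": mean per-window counts `S_bar`, `D_bar`
#' with null variances `var_S = S_bar + theta_L^2 b_n` (Watterson) and
#' `var_D = D_bar + theta_L^2` (divergence with the ancestral-polymorphism
#' term), where `theta_L = S_bar / a_n`.
#'
#' @param counts Grid from [hka_window_counts()].
#' @param n_haplotypes Sample size in haplotypes.
#' @param min_windows Minimum unmasked windows required.
#' @return List of class `hka_background`: `S_bar`, `D_bar`, `a_n`, `b_n`,
#'   `var_S`, `var_D`, `n_windows`.
#' @export
hka_background <- function(counts, n_haplotypes, min_windows = 30) {
  ok <- !is.na(counts$S) & !is.na(counts$D)
  if (sum(ok) < min_windows)
    stop("need >= ", min_windows, " unmasked windows for the background")
  stopifnot(n_haplotypes >= 2)
  i <- seq_len(n_haplotypes - 1)
  a_n <- sum(1 / i)
  b_n <- sum(1 / i^2)
  s_bar <- mean(counts$S[ok])
  d_bar <- mean(counts$D[ok])
  theta_l <- s_bar / a_n
  structure(list(S_bar = s_bar, D_bar = d_bar, a_n = a_n, b_n = b_n,
                 var_S = s_bar + theta_l^2 * b_n,
                 var_D = d_bar + theta_l^2,
                 n_windows = sum(ok)),
            class = "hka_background")
}

#' Chi-square goodness-of-fit of one window against the background
#'
#' `X^2 = (S - S_bar)^2 / var_S + (D - D_bar)^2 / var_D`.
#'
#' @param S,D Window counts.
#' @param bg An [hka_background()].
#' @return The chi-square statistic (vectorized).
#' @export
hka_window_chi2 <- function(S, D, bg) {
  if (bg$var_S <= 0 || bg$var_D <= 0)
    stop("degenerate background: zero variance")
  (S - bg$S_bar)^2 / bg$var_S + (D - bg$D_bar)^2 / bg$var_D
}

#' Chi-square critical value for the HKA decision rule
#'
#' Upper-`alpha` quantile of the chi-square distribution; the scan's
#' default decision rule is X^2 > 5.99 (df = 2, alpha = 0.05).
#'
#' @param df Degrees of freedom.
#' @param alpha Upper tail probability.
#' @return Critical value.
#' @export
hka_critical_value <- function(df = 2, alpha = 0.05) {
  stats::qchisq(1 - alpha, df = df)
}

#' Windowed HKA scan
#'
#' Computes per-window `S`, `D` and X^2 against the genome-average
#' background and flags windows exceeding the chi-square critical value;
#' flagged windows merged (gap 0) form the HKA sweep intervals.
#'
#' @inheritParams hka_window_counts
#' @param alpha Significance level.
#' @param df Degrees of freedom for the critical value (default 2, giving
#'   the canonical 5.99 cut at alpha = 0.05).
#' @param min_windows Passed to [hka_background()].
#' @return Grid with `S`, `D`, `chi2`, `significant`; attributes
#'   `background` and `sweeps` (merged flagged intervals).
#' @export
hka_scan <- function(panel, outgroup, grid, population, alpha = 0.05,
                     df = 2, min_windows = 30) {
  counts <- hka_window_counts(panel, outgroup, grid, population)
  n_hap <- max(allele_counts(panel, population)$n)
  bg <- hka_background(counts, n_hap, min_windows)
  crit <- hka_critical_value(df, alpha)
  out <- counts
  out$chi2 <- hka_window_chi2(counts$S, counts$D, bg)
  out$significant <- !is.na(out$chi2) & out$chi2 > crit
  attr(out, "background") <- bg
  attr(out, "critical_value") <- crit
  attr(out, "sweeps") <- if (any(out$significant)) {
    merge_intervals(interval_set(out$chrom[out$significant],
                                 out$start[out$significant],
                                 out$end[out$significant]), max_gap = 0)
  } else interval_set(character(), numeric(), numeric())
  out
}
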