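# Linkage disequilibrium: pairwise r^2, distance-binned decay curves,
# half-decay distance, and LD-based recent effective population size
# (the t = 1/(2c) generations-ago convention).

#' Pairwise r^2 between SNPs
#'
#' Haplotype mode computes `r^2 = (p_AB - p_A p_B)^2 / (p_A(1-p_A)
#' p_B(1-p_B))` from phased haplotypes; composite mode is the squared
#' Pearson correlation of diploid genotype dosages (no phase needed).
#' Monomorphic SNPs and pairs farther apart than `max_dist` are skipped.
#'
#' @param panel A [haplotype_panel()].
#' @param population Population label.
#' @param max_dist Maximum pair distance, bp (default 500 kb).
#' @param mode `"haplotype"` or `"composite"`.
#' @param max_snps Random subsample cap on SNPs entering the pair set
#'   (memory guard); `Inf` to disable.
#' @param seed Seed for the subsample.
#' @return Data frame with `dist` (bp) and `r2`, one row per retained pair.
#' @export
pairwise_r2 <- function(panel, population, max_dist = 5e5,
                        mode = c("haplotype", "composite"),
                        max_snps = 3000, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "haplotype") {
    if (!panel$phased) stop("haplotype-mode r^2 requires phased data")
    M <- panel$haps[, hap_cols(panel, population), drop = FALSE]
    keep <- rowSums(is.na(M)) == 0
    M <- M[keep, , drop = FALSE]
    pos <- panel$pos[keep]
  } else {
    M <- dosage_matrix(panel)[, panel$pop == population, drop = FALSE]
    pos <- panel$pos
  }
  f <- rowMeans(M, na.rm = TRUE)
  lim <- if (mode == "haplotype") 1 else 2
  poly <- !is.na(f) & f > 0 & f < lim
  M <- M[poly, , drop = FALSE]
  pos <- pos[poly]
  if (nrow(M) < 2) return(data.frame(dist = numeric(), r2 = numeric()))
  if (nrow(M) > max_snps) {
    set.seed(seed)
    idx <- sort(sample.int(nrow(M), max_snps))
    M <- M[idx, , drop = FALSE]
    pos <- pos[idx]
  }
  S <- nrow(M)
  if (mode == "haplotype") {
    n <- ncol(M)
    p <- rowMeans(M)
    pab <- tcrossprod(M) / n
    num <- (pab - outer(p, p))^2
    den <- outer(p * (1 - p), p * (1 - p))
    r2 <- num / den
  } else {
    r2 <- suppressWarnings(stats::cor(t(M), use = "pairwise.complete.obs"))^2
  }
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  d <- abs(pos[ut[, 2]] - pos[ut[, 1]])
  ok <- d <= max_dist & !is.na(r2[ut])
  data.frame(dist = d[ok], r2 = r2[ut][ok])
}

#' LD decay curve: mean r^2 per distance bin
#'
#' @param pairs Data frame from [pairwise_r2()].
#' @param bin_width Bin width, bp.
#' @return Data frame of class `ld_decay`: `bin_start`, `bin_end`,
#'   `bin_mid`, `n_pairs`, `mean_r2` (empty bins omitted).
#' @export
ld_decay_curve <- function(pairs, bin_width = 1000) {
  stopifnot(bin_width >= 1)
  if (!nrow(pairs))
    return(structure(data.frame(bin_start = numeric(), bin_end = numeric(),
                                bin_mid = numeric(), n_pairs = integer(),
                                mean_r2 = numeric()),
                     class = c("ld_decay", "data.frame")))
  b <- floor(pairs$dist / bin_width)
  agg <- stats::aggregate(pairs$r2, by = list(bin = b),
                          FUN = function(x) c(n = length(x), m = mean(x)))
  out <- data.frame(bin_start = agg$bin * bin_width,
                    bin_end = (agg$bin + 1) * bin_width,
                    bin_mid = (agg$bin + 0.5) * bin_width,
                    n_pairs = as.integer(agg$x[, "n"]),
                    mean_r2 = agg$x[, "m"])
  out <- out[order(out$bin_start), ]
  rownames(out) <- NULL
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' Distance at which LD decays to half its maximum
#'
#' The smallest distance at which the binned mean r^2 falls to half the
#' curve's maximum, linearly interpolated between the straddling bin
#' midpoints. A curve that never falls below half-max within range returns
#' `NA` with attribute `sentinel = "> max_dist"`.
#'
#' @param curve An `ld_decay` curve.
#' @return Half-decay distance in bp, or `NA` (sentinel).
#' @export
half_decay_distance <- function(curve) {
  if (!nrow(curve)) stop("empty LD decay curve")
  m <- curve$mean_r2
  half <- max(m) / 2
  i_max <- which.max(m)
  below <- which(m <= half & seq_along(m) >= i_max)
  if (!length(below)) {
    out <- NA_real_
    attr(out, "sentinel") <- "> max_dist"
    return(out)
  }
  j <- below[1]
  if (j == i_max) return(curve$bin_mid[j])
  x0 <- curve$bin_mid[j - 1]; y0 <- m[j - 1]
  x1 <- curve$bin_mid[j]; y1 <- m[j]
  x0 + (y0 - half) / (y0 - y1) * (x1 - x0)
}

#' Recent effective population size from binned LD
#'
#' Per distance bin with mean genetic distance `c` Morgans, the
#' sample-size-adjusted `r^2_adj = mean r^2 - 1/(2 n_individuals)` yields
#' `Ne = (1/(4c)) (1/r^2_adj - alpha)`, interpreted as the effective size
#' `t = 1/(2c)` generations ago. Bins with too few pairs or non-positive
#' adjusted r^2 are masked.
#'
#' @param curve An `ld_decay` curve.
#' @param n_individuals Diploid sample size behind the r^2 values.
#' @param alpha Correction constant: 1, or 2.2 when mutation is accounted
#'   for (default).
#' @param map A [genetic_map()] converting bin midpoints to Morgans.
#' @param min_pairs Minimum pairs per bin.
#' @return Data frame: `c_morgans`, `t_generations`, `r2_adj`, `ne`.
#' @export
ne_from_ld <- function(curve, n_individuals, alpha = 2.2,
                       map = default_genetic_map(), min_pairs = 100) {
  stopifnot(alpha > 0, n_individuals >= 2)
  keep <- curve$n_pairs >= min_pairs
  cv <- curve[keep, , drop = FALSE]
  c_m <- interpolate_cm(map, cv$bin_mid) / 100
  r2_adj <- cv$mean_r2 - 1 / (2 * n_individuals)
  ne <- ifelse(r2_adj > 0 & c_m > 0,
               (1 / (4 * c_m)) * (1 / r2_adj - alpha), NA_real_)
  data.frame(c_morgans = c_m, t_generations = 1 / (2 * c_m),
             r2_adj = r2_adj, ne = ifelse(is.na(ne) | ne <= 0, NA_real_, ne))
}
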