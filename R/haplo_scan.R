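# Extended haplotype homozygosity (EHH), integrated haplotype homozygosity
# (iHH), and the standardized integrated haplotype score (iHS).

#' Extended haplotype homozygosity outward from a core site
#'
#' For the supplied carrier haplotypes, EHH at extent `x` is the probability
#' that two randomly drawn carriers are identical over every site from the
#' core to `x`: `sum_h C(n_h, 2) / C(n_c, 2)` over the distinct extended
#' haplotypes. EHH is 1 at the core and non-increasing outward.
#'
#' @param haps Integer matrix (sites x haplotypes) of phased alleles over
#'   the interval; all columns are carriers of the core allele.
#' @param core Core site row index.
#' @param side `"left"` or `"right"`.
#' @return Data frame with `index` (site row) and `ehh`, starting at the
#'   core (ehh = 1) and moving outward.
#' @export
ehh <- function(haps, core, side = c("left", "right")) {
  side <- match.arg(side)
  haps <- as.matrix(haps)
  nc <- ncol(haps)
  if (nc < 2) stop("EHH needs >= 2 carrier haplotypes")
  if (anyNA(haps)) stop("EHH requires phased, fully called haplotypes")
  dir <- if (side == "left") -1L else 1L
  idx <- core
  e <- 1
  g <- rep(1L, nc)
  j <- core
  denom <- nc * (nc - 1)
  repeat {
    j <- j + dir
    if (j < 1 || j > nrow(haps)) break
    u <- g * 2L + haps[j, ]
    g <- match(u, unique(u))
    tab <- tabulate(g)
    idx <- c(idx, j)
    e <- c(e, sum(tab * (tab - 1)) / denom)
  }
  data.frame(index = idx, ehh = e)
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoid integral of one outward EHH curve against genetic distance
#' (cM), truncated where EHH falls below `cutoff` (the trapezoid into the
#' first sub-cutoff point is included), where the physical extent from the
#' core exceeds `max_extend`, or where an inter-SNP gap exceeds `max_gap`
#' (both flagged).
#'
#' @param ehh_values EHH curve from the core outward; first element must
#'   be 1 (the core).
#' @param cm Genetic positions (cM) aligned with `ehh_values`.
#' @param bp Optional physical positions (bp) for the extent/gap rules.
#' @param cutoff EHH truncation threshold.
#' @param max_extend Maximum physical extent from the core, bp.
#' @param max_gap Maximum tolerated inter-SNP gap, bp.
#' @return List with `ihh` (cM units) and `flag` (0 = clean, 1 = extent or
#'   data-end truncation, 2 = gap truncation).
#' @export
ihh <- function(ehh_values, cm, bp = NULL, cutoff = 0.05, max_extend = 1e6,
                max_gap = 2e5) {
  stopifnot(length(ehh_values) == length(cm))
  if (length(ehh_values) == 0 || ehh_values[1] != 1)
    stop("EHH curve must start at 1 at the core")
  area <- 0
  flag <- 0L
  if (length(ehh_values) >= 2) {
    for (j in 2:length(ehh_values)) {
      if (!is.null(bp)) {
        if (abs(bp[j] - bp[j - 1]) > max_gap) { flag <- bitwOr(flag, 2L); break }
        if (abs(bp[j] - bp[1]) > max_extend) { flag <- bitwOr(flag, 1L); break }
      }
      area <- area + 0.5 * (ehh_values[j - 1] + ehh_values[j]) *
        abs(cm[j] - cm[j - 1])
      if (ehh_values[j] < cutoff) break
      if (j == length(ehh_values) && ehh_values[j] >= cutoff)
        flag <- bitwOr(flag, 1L) # ran off the data above the cutoff
    }
  } else flag <- 1L
  list(ihh = area, flag = flag)
}

# population haplotype matrix with fully called sites only; returns the
# matrix, retained site indices and positions
pop_hap_matrix <- function(panel, population) {
  if (!panel$phased) stop("iHS requires phased haplotypes")
  H <- panel$haps[, hap_cols(panel, population), drop = FALSE]
  keep <- rowSums(is.na(H)) == 0
  list(H = H[keep, , drop = FALSE], keep = which(keep),
       pos = panel$pos[keep])
}

#' Unstandardized iHS at a single core SNP
#'
#' `ln(iHH_ancestral / iHH_derived)`: negative values mean the derived
#' allele sits on unusually long homozygous haplotypes. Implemented through
#' the R-level [ehh()]/[ihh()] path (the genome scan uses the compiled
#' equivalent).
#'
#' @param panel A [haplotype_panel()] with ancestral states.
#' @param population Population label.
#' @param core_pos Core SNP position (1-based bp).
#' @param map A [genetic_map()]; default flat 1 cM/Mb.
#' @param min_carriers Minimum carriers per allele class.
#' @inheritParams ihh
#' @return List with `ihh_a`, `ihh_d`, `uihs`, `flag` (one of `"ok"`,
#'   `"truncated"`, `"gap"`, `"low_freq"`, `"zero_ihh"`).
#' @export
ihs_unstandardized <- function(panel, population, core_pos,
                               map = default_genetic_map(),
                               min_carriers = 3, cutoff = 0.05,
                               max_extend = 1e6, max_gap = 2e5) {
  pm <- pop_hap_matrix(panel, population)
  core <- match(core_pos, pm$pos)
  if (is.na(core)) stop("core position not found among fully called sites")
  site <- pm$keep[core]
  anc_ref <- panel$ancestral_is_ref[site]
  if (is.na(anc_ref)) stop("ancestral state unknown at the core SNP")
  cm <- interpolate_cm(map, pm$pos)
  one_class <- function(allele) {
    carriers <- which(pm$H[core, ] == allele)
    if (length(carriers) < min_carriers) return(NULL)
    tot <- 0; fl <- 0L
    for (s in c("left", "right")) {
      cur <- ehh(pm$H[, carriers, drop = FALSE], core, s)
      r <- ihh(cur$ehh, cm[cur$index], bp = pm$pos[cur$index],
               cutoff = cutoff, max_extend = max_extend, max_gap = max_gap)
      tot <- tot + r$ihh; fl <- bitwOr(fl, r$flag)
    }
    list(ihh = tot, flag = fl)
  }
  der <- if (anc_ref) 1L else 0L
  a <- one_class(1L - der)
  d <- one_class(der)
  if (is.null(a) || is.null(d))
    return(list(ihh_a = NA_real_, ihh_d = NA_real_, uihs = NA_real_,
                flag = "low_freq"))
  flag <- flag_label(bitwOr(a$flag, d$flag))
  if (a$ihh == 0 || d$ihh == 0)
    return(list(ihh_a = a$ihh, ihh_d = d$ihh, uihs = NA_real_,
                flag = "zero_ihh"))
  list(ihh_a = a$ihh, ihh_d = d$ihh, uihs = log(a$ihh / d$ihh), flag = flag)
}

flag_label <- function(bits) {
  ifelse(bitwAnd(bits, 4L) > 0, "low_freq",
         ifelse(bitwAnd(bits, 2L) > 0, "gap",
                ifelse(bitwAnd(bits, 1L) > 0, "truncated", "ok")))
}

#' Genome-wide iHS scan
#'
#' Computes unstandardized iHS at every fully called SNP whose derived
#' allele frequency lies inside `maf_band`, integrating EHH against the
#' genetic map (default 1 cM/Mb). Sites without a known ancestral state are
#' skipped.
#'
#' @param panel A [haplotype_panel()] (phased).
#' @param population Population label.
#' @param map A [genetic_map()].
#' @param maf_band Derived-allele frequency band for core SNPs.
#' @param min_carriers Minimum carriers per allele class (default 3).
#' @inheritParams ihh
#' @return An `ihs_result` data frame: `pos`, `daf`, `ihh_a`, `ihh_d`,
#'   `uihs`, `flag`.
#' @export
ihs_scan <- function(panel, population, map = default_genetic_map(),
                     maf_band = c(0.05, 0.95), min_carriers = 3,
                     cutoff = 0.05, max_extend = 1e6, max_gap = 2e5) {
  pm <- pop_hap_matrix(panel, population)
  anc_ref <- panel$ancestral_is_ref[pm$keep]
  nh <- ncol(pm$H)
  k_alt <- rowSums(pm$H)
  daf <- ifelse(anc_ref, k_alt / nh, 1 - k_alt / nh)
  cores <- which(!is.na(anc_ref) & daf >= maf_band[1] & daf <= maf_band[2])
  cm <- interpolate_cm(map, pm$pos)
  res <- ihh_scan_cpp(pm$H, pm$pos, cm, cores, cutoff, max_extend, max_gap,
                      min_carriers)
  ihh0 <- res$ihh[, 1]; ihh1 <- res$ihh[, 2]
  swap <- !anc_ref[cores] # derived allele is coded 0 at these cores
  ihh_a <- ifelse(swap, ihh1, ihh0)
  ihh_d <- ifelse(swap, ihh0, ihh1)
  flag <- flag_label(res$flags)
  uihs <- ifelse(!is.na(ihh_a) & !is.na(ihh_d) & ihh_a > 0 & ihh_d > 0,
                 log(ihh_a / ihh_d), NA_real_)
  flag[flag == "ok" & is.na(uihs)] <- "zero_ihh"
  out <- data.frame(pos = pm$pos[cores], daf = daf[cores], ihh_a = ihh_a,
                    ihh_d = ihh_d, uihs = uihs, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("ihs_result", "data.frame")
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Within equal-width bins of derived frequency, subtract the bin mean and
#' divide by the bin standard deviation, so that extreme |iHS| is comparable
#' across frequencies. Bins with fewer than `min_bin` clean scores are
#' merged with their neighbour.
#'
#' @param res An `ihs_result` from [ihs_scan()].
#' @param n_bins Number of frequency bins (default 50).
#' @param min_bin Minimum clean scores per bin before merging.
#' @return `res` with added columns `ihs` (standardized; `NA` for QC-fail
#'   SNPs) and `bin`.
#' @export
standardize_ihs <- function(res, n_bins = 50, min_bin = 20) {
  stopifnot(n_bins >= 1)
  ok <- res$flag == "ok" & !is.na(res$uihs)
  if (!any(ok)) stop("no QC-pass scores to standardize")
  rng <- range(res$daf[ok])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  br[1] <- -Inf; br[length(br)] <- Inf
  bin <- as.integer(cut(res$daf, br))
  # merge sparse bins left to right
  repeat {
    counts <- tabulate(bin[ok], nbins = max(bin, na.rm = TRUE))
    occupied <- which(counts > 0)
    sparse <- occupied[counts[occupied] < min_bin]
    if (!length(sparse) || length(occupied) == 1) break
    b <- sparse[1]
    nb <- occupied[occupied != b]
    target <- nb[which.min(abs(nb - b))]
    bin[bin == b] <- target
  }
  res$bin <- bin
  res$ihs <- NA_real_
  for (b in unique(bin[ok])) {
    sel <- ok & bin == b
    mu <- mean(res$uihs[sel]); sdv <- stats::sd(res$uihs[sel])
    if (is.na(sdv) || sdv == 0)
      stop("degenerate frequency bin: zero variance of unstandardized iHS")
    res$ihs[sel] <- (res$uihs[sel] - mu) / sdv
  }
  res
}

#' Window-level summary of extreme iHS scores
#'
#' Per window, the proportion of scored SNPs with `|iHS| > z_threshold`;
#' windows at or above the `(1 - top_fraction)` empirical quantile of that
#' proportion (and with a strictly positive proportion) are flagged
#' significant. Windows with fewer than `min_scored` scored SNPs are masked.
#'
#' @param res A standardized `ihs_result` (see [standardize_ihs()]).
#' @param grid A [make_windows()] grid (the default scan geometry is the
#'   shared 50-kb/25-kb sliding grid; pass a non-overlapping grid — `step ==
#'   size` — for the non-overlapping convention).
#' @param z_threshold |iHS| cut defining "extreme" (default 2).
#' @param top_fraction Upper tail flagged (default 0.05).
#' @param min_scored Minimum scored SNPs per window.
#' @return Grid with `n_scored`, `prop_extreme`, `significant`.
#' @export
ihs_window_summary <- function(res, grid, z_threshold = 2,
                               top_fraction = 0.05, min_scored = 10) {
  scored <- !is.na(res$ihs)
  pos0 <- res$pos - 1
  n_scored <- window_sum(as.numeric(scored), pos0, grid)
  n_extreme <- window_sum(as.numeric(scored & abs(res$ihs) > z_threshold),
                          pos0, grid)
  out <- grid
  out$n_scored <- n_scored
  out$prop_extreme <- ifelse(n_scored >= min_scored, n_extreme / n_scored,
                             NA_real_)
  vals <- out$prop_extreme
  if (all(is.na(vals))) {
    out$significant <- FALSE
    return(out)
  }
  thr <- empirical_threshold(vals[!is.na(vals)], top_fraction)
  out$significant <- !is.na(vals) & vals >= thr & vals > 0
  attr(out, "threshold") <- thr
  out
}
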