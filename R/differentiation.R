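# Population differentiation: Weir-Cockerham F_ST on allele counts, V_ST on
# CNV intensity, Reynolds and p-distances, neighbor-joining trees and
# bootstrap support.

#' Weir-Cockerham F_ST variance components at one site
#'
#' The Weir-Cockerham (1984) analysis-of-variance estimator applied to
#' haploid-coded allele counts: alleles are the sampling units, so the
#' genotypic (heterozygosity) component is zero. Returns the
#' between-population component `a`, within component `b`, `c = 0`, and
#' `fst = a / (a + b + c)` (`NA` when the total variance is zero).
#'
#' @param derived Per-population derived-allele counts.
#' @param total Per-population called-allele counts.
#' @return List with `a`, `b`, `c`, `fst`.
#' @export
wc_fst_site <- function(derived, total) {
  r <- length(total)
  if (r < 2) stop("wc_fst_site needs >= 2 populations")
  stopifnot(length(derived) == r, all(total >= 2), all(derived >= 0),
            all(derived <= total))
  N <- sum(total)
  p <- derived / total
  pbar <- sum(derived) / N
  msb <- sum(total * (p - pbar)^2) / (r - 1)
  msw <- sum(total * p * (1 - p)) / (N - r)
  n_c <- (N - sum(total^2) / N) / (r - 1)
  a <- (msb - msw) / n_c
  b <- msw
  tot <- a + b
  list(a = a, b = b, c = 0,
       fst = if (tot == 0) NA_real_ else a / tot)
}

# vectorized per-site WC components across a panel
wc_fst_sites <- function(panel, populations = NULL) {
  if (is.null(populations)) populations <- levels(panel$pop)
  if (length(populations) < 2) stop("need >= 2 populations")
  K <- sapply(populations, function(p) allele_counts(panel, p)$k)
  Nn <- sapply(populations, function(p) allele_counts(panel, p)$n)
  if (is.null(dim(K))) { K <- matrix(K, 1); Nn <- matrix(Nn, 1) }
  P <- K / Nn
  P[Nn == 0] <- 0
  N <- rowSums(Nn)
  r_eff <- rowSums(Nn > 0)
  pbar <- rowSums(K) / N
  msb <- rowSums(Nn * (P - pbar)^2) / (r_eff - 1)
  msw <- rowSums(Nn * P * (1 - P)) / (N - r_eff)
  n_c <- (N - rowSums(Nn^2) / N) / (r_eff - 1)
  bad <- r_eff < 2 | (N - r_eff) < 1 | n_c <= 0
  a <- (msb - msw) / n_c
  b <- msw
  a[bad] <- NA_real_; b[bad] <- NA_real_
  fst <- ifelse(!bad & (a + b) != 0, a / (a + b), NA_real_)
  data.frame(pos = panel$pos, a = a, b = b, c = 0, fst = fst)
}

#' Windowed F_ST from per-site variance components
#'
#' Two pooling modes: `"mean"` averages per-site F_ST ratios over unmasked
#' sites (the "global F_ST, measured by the average value for each SNP"
#' convention), `"ratio"` is the ratio of summed components
#' `sum(a) / sum(a+b+c)` (the weighted/vcftools convention).
#'
#' @param sites Data frame from the per-site scan (columns `pos`, `a`, `b`,
#'   `c`, `fst`).
#' @param grid A [make_windows()] grid.
#' @param mode `"mean"` or `"ratio"`.
#' @return The grid with columns `n_snps` and `fst`.
#' @export
window_fst <- function(sites, grid, mode = c("mean", "ratio")) {
  mode <- match.arg(mode)
  pos0 <- sites$pos - 1
  ok <- !is.na(sites$fst)
  out <- grid
  n_ok <- window_sum(as.numeric(ok), pos0, grid)
  out$n_snps <- n_ok
  if (mode == "mean") {
    s <- window_sum(ifelse(ok, sites$fst, 0), pos0, grid)
    out$fst <- ifelse(n_ok > 0, s / n_ok, NA_real_)
  } else {
    num <- window_sum(ifelse(ok, sites$a, 0), pos0, grid)
    den <- window_sum(ifelse(ok, sites$a + sites$b + sites$c, 0), pos0, grid)
    out$fst <- ifelse(n_ok > 0 & den != 0, num / den, NA_real_)
  }
  out
}

#' Windowed F_ST scan over a panel
#'
#' @param panel A [haplotype_panel()].
#' @param grid A [make_windows()] grid.
#' @param populations Populations to contrast (default: all).
#' @inheritParams window_fst
#' @return Grid with `fst`; attribute `global_fst` carries the genome-wide
#'   per-SNP average.
#' @export
fst_scan <- function(panel, grid, populations = NULL,
                     mode = c("mean", "ratio")) {
  sites <- wc_fst_sites(panel, populations)
  out <- window_fst(sites, grid, mode)
  attr(out, "global_fst") <- mean(sites$fst, na.rm = TRUE)
  out
}

#' V_ST: population differentiation of CNV intensity
#'
#' `(V_T - V_S) / V_T` where `V_T` is the variance of the intensity values
#' over all individuals of both populations and `V_S` the
#' population-size-weighted average of the two within-population variances.
#' Population variances divide by `n`. Negative raw values are clipped to 0;
#' `V_T = 0` is masked (`NA`).
#'
#' @param depth Numeric intensity values (one CNV region), one per
#'   individual.
#' @param pop Factor with two levels aligned with `depth`.
#' @return V_ST in `[0, 1]`, or `NA` when masked.
#' @export
vst <- function(depth, pop) {
  pop <- droplevels(factor(pop))
  if (nlevels(pop) != 2) stop("vst contrasts exactly 2 populations")
  if (any(table(pop) < 2)) stop("each population needs >= 2 individuals")
  if (anyNA(depth)) stop("depth values must be finite")
  pvar <- function(x) mean((x - mean(x))^2)
  v_t <- pvar(depth)
  if (v_t == 0) return(NA_real_)
  n <- tabulate(pop)
  v_s <- sum(n * tapply(depth, pop, pvar)) / sum(n)
  min(max((v_t - v_s) / v_t, 0), 1)
}

#' Per-region V_ST scan over a CNV matrix
#'
#' @param cnv A `cnv_matrix` from [simulate_cnv_matrix()] or assembled from
#'   a read-depth TSV.
#' @param populations The two population labels (default: the matrix's two
#'   levels).
#' @return Data frame: region coordinates, `vst`, `n1`, `n2`.
#' @export
vst_scan <- function(cnv, populations = NULL) {
  if (is.null(populations)) populations <- levels(cnv$pop)[1:2]
  keep <- cnv$pop %in% populations
  pop <- droplevels(cnv$pop[keep])
  v <- apply(cnv$depth[keep, , drop = FALSE], 2, vst, pop = pop)
  cbind(as.data.frame(cnv$regions),
        data.frame(vst = v, n1 = sum(pop == populations[1]),
                   n2 = sum(pop == populations[2])))
}

#' Read / write a CNV intensity matrix TSV
#'
#' One row per individual: columns `individual`, `population`, then one
#' column per CNV region named `chrom:start-end` (0-based half-open).
#'
#' @param path TSV file.
#' @return A `cnv_matrix` list (`regions`, `depth`, `pop`, `truth = NULL`).
#' @export
read_cnv_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  stopifnot(all(c("individual", "population") %in% names(tab)))
  rcols <- setdiff(names(tab), c("individual", "population"))
  m <- regmatches(rcols, regexec("^(.+):([0-9]+)-([0-9]+)$", rcols))
  if (any(lengths(m) != 4)) stop("region columns must be named chrom:start-end")
  regions <- interval_set(chrom = vapply(m, `[`, "", 2),
                          start = as.numeric(vapply(m, `[`, "", 3)),
                          end = as.numeric(vapply(m, `[`, "", 4)),
                          name = rcols)
  depth <- as.matrix(tab[rcols])
  rownames(depth) <- tab$individual
  structure(list(regions = regions, depth = depth,
                 pop = factor(tab$population), truth = NULL),
            class = "cnv_matrix")
}

#' @rdname read_cnv_matrix
#' @param cnv A `cnv_matrix`.
#' @export
write_cnv_matrix <- function(cnv, path) {
  tab <- data.frame(individual = rownames(cnv$depth),
                    population = as.character(cnv$pop),
                    cnv$depth, check.names = FALSE)
  names(tab)[-(1:2)] <- sprintf("%s:%d-%d", cnv$regions$chrom,
                                as.integer(cnv$regions$start),
                                as.integer(cnv$regions$end))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reynolds coancestry distance between populations
#'
#' For each pair of populations, the coancestry estimate
#' `theta = sum_l sum_a (p1a - p2a)^2 / (2 sum_l (1 - sum_a p1a p2a))`
#' over loci, transformed to `D = -ln(1 - theta)`; `theta >= 1` yields
#' `Inf`.
#'
#' @param freqs Matrix of allele-1 frequencies, populations x loci
#'   (biallelic loci; the second allele's frequency is the complement).
#' @return Symmetric labelled distance matrix.
#' @export
reynolds_distance <- function(freqs) {
  freqs <- as.matrix(freqs)
  np <- nrow(freqs)
  if (np < 2) stop("need >= 2 populations")
  labs <- rownames(freqs)
  if (is.null(labs)) labs <- paste0("pop", seq_len(np))
  D <- matrix(0, np, np, dimnames = list(labs, labs))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    p1 <- freqs[i, ]; p2 <- freqs[j, ]
    num <- sum((p1 - p2)^2 + ((1 - p1) - (1 - p2))^2)
    den <- 2 * sum(1 - (p1 * p2 + (1 - p1) * (1 - p2)))
    theta <- if (den > 0) num / den else 0
    D[i, j] <- D[j, i] <- if (theta >= 1) Inf else -log(1 - theta)
  }
  D
}

# population x site matrix of alt-allele frequencies
pop_freqs <- function(panel, populations = NULL) {
  if (is.null(populations)) populations <- levels(panel$pop)
  f <- t(sapply(populations, function(p) {
    ac <- allele_counts(panel, p)
    ifelse(ac$n > 0, ac$k / ac$n, NA_real_)
  }))
  rownames(f) <- populations
  f
}

# diploid dosage matrix, sites x individuals; NA when either haplotype is
# missing
dosage_matrix <- function(panel) {
  h <- panel$haps
  odd <- seq(1, ncol(h), by = 2)
  d <- h[, odd, drop = FALSE] + h[, odd + 1, drop = FALSE]
  colnames(d) <- panel$individuals
  d
}

#' Pairwise p-distance between individuals
#'
#' Allele-sharing mismatch between diploid genotypes: per site, 0 for equal
#' dosage, 0.5 for one shared allele, 1 for opposite homozygotes; averaged
#' over pairwise-complete sites.
#'
#' @param panel A [haplotype_panel()].
#' @return Symmetric labelled distance matrix over individuals (`NA` entries
#'   where a pair shares no called site).
#' @export
p_distance_matrix <- function(panel) {
  dos <- dosage_matrix(panel)
  pdist_from_dosage(dos)
}

pdist_from_dosage <- function(dos) {
  n <- ncol(dos)
  D <- matrix(0, n, n, dimnames = list(colnames(dos), colnames(dos)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- abs(dos[, i] - dos[, j]) / 2
    D[i, j] <- D[j, i] <- mean(dd, na.rm = TRUE)
  }
  D[is.nan(D)] <- NA_real_
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Negative branch
#' lengths at a join are set to zero with the deficit transferred to the
#' sister branch; the final three-taxon resolution uses the closed-form
#' lengths clamped at zero. Additive distance matrices are reconstructed
#' exactly (topology and branch lengths).
#'
#' @param d Symmetric distance matrix (or `dist`) with labels; >= 3 taxa,
#'   finite entries.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("nj_tree needs >= 3 taxa")
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  nodes <- labs
  D <- unname(d)
  while (length(nodes) > 3) {
    m <- length(nodes)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    ij <- arrayInd(which.min(Q), dim(Q))
    i <- min(ij); j <- max(ij)
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }
    newd <- (D[i, ] + D[j, ] - dij) / 2
    lab <- sprintf("(%s:%.15g,%s:%.15g)", nodes[i], li, nodes[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nodes <- c(nodes[keep], lab)
  }
  dxy <- D[1, 2]; dxz <- D[1, 3]; dyz <- D[2, 3]
  lx <- max((dxy + dxz - dyz) / 2, 0)
  ly <- max((dxy + dyz - dxz) / 2, 0)
  lz <- max((dxz + dyz - dxy) / 2, 0)
  ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                                nodes[1], lx, nodes[2], ly, nodes[3], lz))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Sites are resampled with replacement `n_reps` times; the support of each
#' internal edge of the point-estimate tree is the percentage of replicate
#' trees containing the same bipartition.
#'
#' @param panel A [haplotype_panel()].
#' @param n_reps Number of bootstrap replicates (the scan convention is
#'   1000).
#' @param distance `"p"` for the individual-based p-distance tree,
#'   `"reynolds"` for the population tree on Reynolds distances.
#' @param seed Integer seed.
#' @return The point-estimate `phylo` tree with `node.label` set to percent
#'   support.
#' @export
bootstrap_support <- function(panel, n_reps = 100,
                              distance = c("p", "reynolds"), seed = 1) {
  distance <- match.arg(distance)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  if (distance == "p") {
    dos <- dosage_matrix(panel)
    dist_of <- function(idx) pdist_from_dosage(dos[idx, , drop = FALSE])
  } else {
    f <- pop_freqs(panel)
    dist_of <- function(idx) reynolds_distance(f[, idx, drop = FALSE])
  }
  S <- n_sites(panel)
  point_d <- dist_of(seq_len(S))
  if (anyNA(point_d)) stop("distance matrix has masked entries; cannot build tree")
  point <- nj_tree(point_d)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    db <- dist_of(sample.int(S, S, replace = TRUE))
    db[is.na(db)] <- 0
    reps[[b]] <- nj_tree(db)
  }
  cnt <- ape::prop.clades(point, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  point$node.label <- round(100 * cnt / n_reps)
  point
}
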