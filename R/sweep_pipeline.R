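# Thresholding, multi-statistic intersection, sweep merging and annotation,
# permutation significance for annotation overlap, and the end-to-end
# pipeline driver.

#' Empirical top-fraction threshold
#'
#' Nearest-rank `(1 - top_fraction)` quantile with the higher-rank
#' tie-break: exactly `ceiling(top_fraction * n)` values sit at or above
#' the threshold when there are no ties.
#'
#' @param values Unmasked statistic values.
#' @param top_fraction Upper-tail fraction in (0, 1); the scan convention
#'   is 0.01 for XP-CLR and the diversity ratio, 0.05 for iHS windows.
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values are masked")
  if (length(unique(v)) == 1)
    warning("all values identical; every window sits at the threshold")
  n <- length(v)
  k <- n - ceiling(top_fraction * n) + 1
  sort(v, partial = k)[k]
}

#' Flag the top fraction of windows
#'
#' @inheritParams empirical_threshold
#' @return Logical vector aligned with `values` (`FALSE` where masked);
#'   attribute `threshold`.
#' @export
flag_top <- function(values, top_fraction) {
  thr <- empirical_threshold(values, top_fraction)
  out <- !is.na(values) & values >= thr
  attr(out, "threshold") <- thr
  out
}

#' Intersect flagged window sets
#'
#' @param flagged Named list of logical vectors on the same window grid.
#' @param combination Character vector naming the statistics to intersect.
#' @return Logical vector: windows flagged by every named statistic.
#' @export
intersect_statistics <- function(flagged, combination) {
  bad <- setdiff(combination, names(flagged))
  if (length(bad)) stop("unknown statistic name(s): ",
                        paste(bad, collapse = ", "))
  lens <- unique(vapply(flagged[combination], length, integer(1)))
  if (length(lens) != 1) stop("flagged sets are not on the same grid")
  Reduce(`&`, flagged[combination])
}

#' Region-level combination of two flagged window sets
#'
#' Each statistic's flagged windows are merged (gap 0) into candidate
#' regions; the combination is the interval intersection of the two region
#' sets (>= 1 bp). This is the region-level sense in which scans combine
#' statistics — two statistics whose peaks sit in adjacent, overlapping
#' sliding windows still agree on the region.
#'
#' @param grid Window grid.
#' @param flagged_a,flagged_b Logical vectors over the grid's windows.
#' @return An [interval_set()] of jointly supported regions.
#' @export
intersect_flagged_regions <- function(grid, flagged_a, flagged_b) {
  if (!any(flagged_a, na.rm = TRUE) || !any(flagged_b, na.rm = TRUE))
    return(interval_set(character(), numeric(), numeric()))
  ra <- merge_intervals(interval_set(grid$chrom[which(flagged_a)],
                                     grid$start[which(flagged_a)],
                                     grid$end[which(flagged_a)]), 0)
  rb <- merge_intervals(interval_set(grid$chrom[which(flagged_b)],
                                     grid$start[which(flagged_b)],
                                     grid$end[which(flagged_b)]), 0)
  gr <- GenomicRanges::intersect(as_granges(ra), as_granges(rb))
  if (!length(gr)) return(interval_set(character(), numeric(), numeric()))
  from_granges(gr)
}

#' Merge flagged windows into sweeps and annotate with nearby features
#'
#' Flagged windows are merged (gap 0) into candidate sweep intervals;
#' features overlapping a sweep, or lying within `flank` bp of one, are
#' listed per sweep (relation `"overlap"` or `"near"`).
#'
#' @param grid Window grid carrying the flags.
#' @param flagged Logical vector over the grid's windows.
#' @param genes An [interval_set()] of features (e.g. genes), or `NULL`.
#' @param flank Distance in bp defining "near" (default 20 kb, the locus
#'   window convention).
#' @return List: `sweeps` ([interval_set()]), `genes` (data frame
#'   `sweep_idx`, `gene`, `relation`).
#' @export
merge_and_annotate <- function(grid, flagged, genes = NULL, flank = 20000) {
  stopifnot(flank >= 0, length(flagged) == nrow(grid))
  if (!any(flagged, na.rm = TRUE))
    return(list(sweeps = interval_set(character(), numeric(), numeric()),
                genes = data.frame(sweep_idx = integer(), gene = character(),
                                   relation = character())))
  sel <- which(flagged)
  sweeps <- merge_intervals(interval_set(grid$chrom[sel], grid$start[sel],
                                         grid$end[sel]), max_gap = 0)
  annotate_sweeps(sweeps, genes, flank)
}

# gene annotation for an already-merged sweep interval set
annotate_sweeps <- function(sweeps, genes = NULL, flank = 20000) {
  sweeps$name <- sprintf("sweep_%03d", seq_len(nrow(sweeps)))
  ann <- data.frame(sweep_idx = integer(), gene = character(),
                    relation = character())
  if (!is.null(genes) && nrow(genes)) {
    direct <- intersect_intervals(sweeps, genes)
    widened <- interval_set(sweeps$chrom, pmax(0, sweeps$start - flank),
                            sweeps$end + flank)
    nearby <- intersect_intervals(widened, genes)
    rel <- rbind(
      if (nrow(direct)) data.frame(sweep_idx = direct$a_idx,
                                   gene = genes$name[direct$b_idx],
                                   relation = "overlap"),
      if (nrow(nearby)) data.frame(sweep_idx = nearby$a_idx,
                                   gene = genes$name[nearby$b_idx],
                                   relation = "near"))
    if (!is.null(rel) && nrow(rel)) {
      rel <- rel[order(rel$sweep_idx, rel$gene,
                       rel$relation != "overlap"), ]
      ann <- rel[!duplicated(rel[c("sweep_idx", "gene")]), ]
      rownames(ann) <- NULL
    }
  }
  list(sweeps = sweeps, genes = ann)
}

# do intervals (s, e) on one chromosome overlap any merged annotation?
overlaps_any <- function(s, e, ann_start, ann_end) {
  if (!length(ann_start)) return(rep(FALSE, length(s)))
  idx <- findInterval(s, ann_start)
  inside <- idx >= 1 & ifelse(idx >= 1, ann_end[pmax(idx, 1)] > s, FALSE)
  nxt <- idx + 1
  ahead <- nxt <= length(ann_start) &
    ann_start[pmin(nxt, length(ann_start))] < e
  inside | ahead
}

#' Permutation test for interval-set overlap
#'
#' The statistic is the number of observed regions overlapping (>= 1 bp) at
#' least one annotation region. The null preserves chromosome assignment,
#' region count and region lengths, placing each region uniformly at random
#' on its chromosome; the add-one p-value is
#' `(1 + #(null >= observed)) / (1 + n_reps)`.
#'
#' @param observed An [interval_set()] (e.g. merged sweeps).
#' @param annotation An [interval_set()] (e.g. QTLs).
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_reps Number of random placements (the scan convention is
#'   10,000).
#' @param seed Integer seed.
#' @return List of class `perm_test`: `observed`, `null` (integer vector),
#'   `p_value`, `n_reps`.
#' @export
permutation_overlap_test <- function(observed, annotation, genome,
                                     n_reps = 1000, seed = 1) {
  stopifnot(n_reps >= 1)
  if (is.null(names(genome))) stop("genome must be a named length vector")
  w <- observed$end - observed$start
  len <- genome[observed$chrom]
  if (anyNA(len)) stop("observed chromosome absent from genome lengths")
  if (any(w > len)) stop("an observed interval is longer than its chromosome")
  ann <- if (nrow(annotation)) merge_intervals(annotation, 0) else annotation
  set.seed(seed)

  count_by_chrom <- function(starts, ends, chroms) {
    tot <- 0L
    for (ch in unique(chroms)) {
      sel <- chroms == ch
      asel <- ann$chrom == ch
      tot <- tot + sum(overlaps_any(starts[sel], ends[sel],
                                    ann$start[asel], ann$end[asel]))
    }
    tot
  }
  obs <- if (nrow(observed)) count_by_chrom(observed$start, observed$end,
                                            observed$chrom) else 0L
  null <- integer(n_reps)
  n_iv <- nrow(observed)
  for (b in seq_len(n_reps)) {
    s <- floor(stats::runif(n_iv) * (len - w + 1))
    null[b] <- count_by_chrom(s, s + w, observed$chrom)
  }
  p <- (1 + sum(null >= obs)) / (1 + n_reps)
  structure(list(observed = obs, null = null, p_value = p, n_reps = n_reps),
            class = "perm_test")
}

#' Majority-rule outgroup allele from a panel population
#'
#' Collapses one population (e.g. the wild outgroup sample) to a per-site
#' consensus allele for the polymorphism/divergence test.
#'
#' @param panel A [haplotype_panel()].
#' @param population Population label.
#' @return Integer per site: 0 (ref), 1 (alt), `NA` when uncalled; ties go
#'   to the ref allele.
#' @export
outgroup_from_population <- function(panel, population) {
  ac <- allele_counts(panel, population)
  ifelse(ac$n == 0, NA_integer_, as.integer(ac$k > ac$n / 2))
}

#' Run the end-to-end selective-sweep pipeline
#'
#' Reads a phased VCF and population map, computes the requested window
#' statistics (`"pi_ratio"`, `"xpclr"`, `"ihs"`, `"hka"`, `"fst"`),
#' applies empirical thresholds, intersects the flagged window sets, merges
#' the headline intersection (XP-CLR with the diversity ratio, when both
#' are present, otherwise the first statistic) into sweeps, annotates them
#' against a gene BED, and permutation-tests QTL overlap. All outputs are
#' written under `config$out_dir` with an md5 manifest; runs are
#' deterministic given the config.
#'
#' @param config A named list or path to a JSON file. Required: `vcf`,
#'   `pop_map`, `chrom_length`, `ref_pop`, `target_pop`. Optional:
#'   `statistics` (default all four scan statistics), `window_size` (50000),
#'   `window_step` (25000), `top_fraction` (0.01), `ihs_top_fraction`
#'   (0.05), `alpha` (0.05), `df` (2), `min_snps` (10), `max_missing`
#'   (0.1), `min_maf` (0.05), `genes_bed`, `qtl_bed`, `flank` (20000),
#'   `n_perm` (1000), `seed` (1), `hka_outgroup` (population collapsed to
#'   the outgroup consensus; default `ref_pop`), `out_dir`.
#' @return A list of class `sweep_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(statistics = c("pi_ratio", "xpclr", "ihs", "hka"),
                   window_size = 50000, window_step = 25000,
                   top_fraction = 0.01, ihs_top_fraction = 0.05,
                   alpha = 0.05, df = 2, min_snps = 10, max_missing = 0.1,
                   min_maf = 0.05, flank = 20000, n_perm = 1000, seed = 1,
                   out_dir = NULL, genes_bed = NULL, qtl_bed = NULL,
                   hka_outgroup = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("vcf", "pop_map", "chrom_length", "ref_pop", "target_pop"))
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  panel_raw <- stage("read_vcf", read_vcf(config$vcf, config$pop_map))
  panel <- stage("filter", filter_variants(panel_raw, config$max_missing,
                                           config$min_maf))
  grid <- make_windows(config$chrom_length, config$window_size,
                       config$window_step, chrom = panel$chrom)
  map <- default_genetic_map(chrom = panel$chrom)

  windows <- grid
  flagged <- list()
  thresholds <- list()

  if ("pi_ratio" %in% config$statistics) {
    pc <- stage("pi_control", window_pi(panel, grid, config$ref_pop))
    pt <- stage("pi_target", window_pi(panel, grid, config$target_pop))
    pr <- pi_ratio_log2(pc, pt, min_snps = config$min_snps)
    windows$pi_control <- pc$pi
    windows$pi_target <- pt$pi
    windows$pi_ratio_log2 <- pr$pi_ratio_log2
    fl <- flag_top(pr$pi_ratio_log2, config$top_fraction)
    flagged$pi_ratio <- as.logical(fl)
    thresholds$pi_ratio <- attr(fl, "threshold")
  }
  if ("xpclr" %in% config$statistics) {
    xs <- stage("xpclr", xpclr_scan(panel, config$ref_pop,
                                    config$target_pop, grid, map))
    windows$xpclr <- xs$windows$xpclr
    fl <- flag_top(windows$xpclr, config$top_fraction)
    flagged$xpclr <- as.logical(fl)
    thresholds$xpclr <- attr(fl, "threshold")
  }
  if ("ihs" %in% config$statistics) {
    ih <- stage("ihs", standardize_ihs(ihs_scan(panel, config$target_pop,
                                                map)))
    ws <- ihs_window_summary(ih, grid, top_fraction = config$ihs_top_fraction,
                             min_scored = config$min_snps)
    windows$ihs_prop_extreme <- ws$prop_extreme
    flagged$ihs <- ws$significant
    thresholds$ihs <- attr(ws, "threshold")
  }
  if ("hka" %in% config$statistics) {
    og_pop <- if (is.null(config$hka_outgroup)) config$ref_pop else
      config$hka_outgroup
    og <- outgroup_from_population(panel_raw, og_pop)
    hk <- stage("hka", hka_scan(panel_raw, og, grid, config$target_pop,
                                alpha = config$alpha, df = config$df))
    windows$hka_chi2 <- hk$chi2
    flagged$hka <- hk$significant
    thresholds$hka <- attr(hk, "critical_value")
  }
  if ("fst" %in% config$statistics) {
    fs <- stage("fst", fst_scan(panel, grid,
                                c(config$ref_pop, config$target_pop)))
    windows$fst <- fs$fst
    fl <- flag_top(windows$fst, config$top_fraction)
    flagged$fst <- as.logical(fl)
    thresholds$fst <- attr(fl, "threshold")
  }

  combos <- list()
  if (length(flagged) >= 2) {
    nms <- names(flagged)
    for (k in 2:length(nms)) {
      for (cmb in utils::combn(nms, k, simplify = FALSE))
        combos[[paste(cmb, collapse = "&")]] <-
          intersect_statistics(flagged, cmb)
    }
  }

  # headline combination: region-level intersection of the XP-CLR and
  # diversity-ratio flag sets when both ran, else the first statistic
  genes <- if (!is.null(config$genes_bed)) read_bed(config$genes_bed)
  ma <- if (all(c("xpclr", "pi_ratio") %in% names(flagged))) {
    reg <- intersect_flagged_regions(grid, flagged$xpclr, flagged$pi_ratio)
    if (nrow(reg)) annotate_sweeps(reg, genes, config$flank)
    else list(sweeps = reg,
              genes = data.frame(sweep_idx = integer(), gene = character(),
                                 relation = character()))
  } else merge_and_annotate(grid, flagged[[1]], genes, config$flank)

  perm <- NULL
  if (!is.null(config$qtl_bed) && nrow(ma$sweeps)) {
    qtl <- read_bed(config$qtl_bed)
    genome <- stats::setNames(config$chrom_length, grid$chrom[1])
    perm <- stage("permutation",
                  permutation_overlap_test(ma$sweeps, qtl, genome,
                                           n_reps = config$n_perm,
                                           seed = config$seed))
  }

  report <- structure(
    list(windows = windows, thresholds = thresholds, flagged = flagged,
         intersections = combos, sweeps = ma$sweeps, genes = ma$genes,
         permutation = perm, config = config,
         n_sites = n_sites(panel), n_sites_raw = n_sites(panel_raw)),
    class = "sweep_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @exportS3Method base::print
print.sweep_report <- function(x, ...) {
  cat("sweep_report:", nrow(x$windows), "windows;",
      length(x$flagged), "statistics (",
      paste(names(x$flagged), collapse = ", "), ");",
      nrow(x$sweeps), "merged sweeps\n")
  if (!is.null(x$permutation))
    cat("QTL overlap:", x$permutation$observed, "regions, permutation p =",
        format(x$permutation$p_value), "\n")
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wpath <- file.path(dir, "windows.tsv")
  write_window_tsv(report$windows, wpath)
  files <- c(files, wpath)
  fpath <- file.path(dir, "flagged.tsv")
  utils::write.table(
    cbind(report$windows[c("chrom", "start", "end")],
          as.data.frame(report$flagged)),
    fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, fpath)
  spath <- file.path(dir, "sweeps.bed")
  write_bed(report$sweeps, spath)
  files <- c(files, spath)
  if (nrow(report$genes)) {
    gpath <- file.path(dir, "sweep_genes.tsv")
    utils::write.table(report$genes, gpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, gpath)
  }
  if (!is.null(report$permutation)) {
    ppath <- file.path(dir, "permutation.json")
    jsonlite::write_json(report$permutation[c("observed", "p_value",
                                              "n_reps")],
                         ppath, auto_unbox = TRUE, digits = NA)
    files <- c(files, ppath)
  }
  cfg <- report$config
  cfg$out_dir <- NULL # manifests compare equal across output locations
  manifest <- list(
    config = cfg,
    thresholds = report$thresholds,
    n_sites = report$n_sites,
    n_sites_raw = report$n_sites_raw,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
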