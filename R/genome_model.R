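# Core genomic data model: haplotype panels, sliding windows, genetic maps
# and interval algebra. Internal coordinates are 0-based half-open
# throughout; VCF positions (1-based) are converted at the I/O boundary.

#' Construct a phased haplotype panel
#'
#' The substrate of every SNP statistic in the package: biallelic sites on a
#' single chromosome with phased (or flagged-unphased) diploid genotypes and
#' a population label per individual.
#'
#' @param chrom Chromosome identifier (scalar).
#' @param pos 1-based bp positions, strictly increasing.
#' @param ref,alt Single-character alleles per site.
#' @param haps Integer matrix, sites x (2 * individuals), entries 0 (ref),
#'   1 (alt) or `NA` (missing). Columns are individual 1 haplotype A,
#'   individual 1 haplotype B, individual 2 haplotype A, ...
#' @param individuals Character vector of sample identifiers.
#' @param pop Population label per individual (character or factor).
#' @param ancestral_is_ref Optional logical per site: is the reference allele
#'   ancestral? `NA` where unknown.
#' @param phased Logical scalar; haplotype-based statistics refuse unphased
#'   panels.
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, pos, ref, alt, haps, individuals, pop,
                            ancestral_is_ref = NULL, phased = TRUE) {
  pos <- as.numeric(pos)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  n_ind <- length(individuals)
  if (length(pos) && any(diff(pos) <= 0))
    stop("positions must be strictly increasing within a chromosome")
  if (nrow(haps) != length(pos))
    stop("haps must have one row per site")
  if (ncol(haps) != 2L * n_ind)
    stop("haps must have 2 columns per individual")
  bad <- haps[!is.na(haps)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("allele indicators must be 0, 1 or NA")
  if (length(pop) != n_ind)
    stop("pop must give one label per individual")
  if (is.null(ancestral_is_ref))
    ancestral_is_ref <- rep(NA, length(pos))
  structure(
    list(chrom = as.character(chrom)[1], pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         haps = haps, individuals = as.character(individuals),
         pop = factor(pop), ancestral_is_ref = as.logical(ancestral_is_ref),
         phased = isTRUE(phased)),
    class = "haplotype_panel")
}

#' @exportS3Method base::print
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel: ", length(x$pos), " sites, ",
      length(x$individuals), " individuals (",
      paste(sprintf("%s=%d", levels(x$pop), tabulate(x$pop)), collapse = ", "),
      "), chrom ", x$chrom, ", ",
      if (x$phased) "phased" else "UNPHASED", "\n", sep = "")
  invisible(x)
}

n_sites <- function(panel) length(panel$pos)

# haplotype column indices for a population (or all columns when NULL)
hap_cols <- function(panel, population = NULL) {
  if (is.null(population)) return(seq_len(ncol(panel$haps)))
  keep <- which(panel$pop == population)
  if (!length(keep)) stop("unknown population: ", population)
  as.vector(rbind(2L * keep - 1L, 2L * keep))
}

# per-site derived(=alt) count k and called-allele count n for a population
allele_counts <- function(panel, population = NULL) {
  h <- panel$haps[, hap_cols(panel, population), drop = FALSE]
  k <- rowSums(h, na.rm = TRUE)
  n <- rowSums(!is.na(h))
  list(k = k, n = n)
}

subset_sites <- function(panel, keep) {
  panel$pos <- panel$pos[keep]
  panel$ref <- panel$ref[keep]
  panel$alt <- panel$alt[keep]
  panel$haps <- panel$haps[keep, , drop = FALSE]
  panel$ancestral_is_ref <- panel$ancestral_is_ref[keep]
  panel
}

#' Filter sites on missingness and minor allele frequency
#'
#' Retains sites whose missing-genotype proportion is strictly below
#' `max_missing` and whose minor allele frequency (over all called alleles in
#' the whole panel) is at least `min_maf`, mirroring the usual pre-analysis
#' SNP filter (missing rate >= 0.1 or MAF < 0.05 removed).
#'
#' @param panel A [haplotype_panel()].
#' @param max_missing Maximum tolerated missing proportion (exclusive bound).
#' @param min_maf Minimum minor allele frequency (inclusive bound).
#' @return The filtered panel; site order is preserved.
#' @export
filter_variants <- function(panel, max_missing = 0.1, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  if (!n_sites(panel)) return(panel)
  ac <- allele_counts(panel)
  ntot <- ncol(panel$haps)
  miss <- 1 - ac$n / ntot
  maf <- ifelse(ac$n > 0, pmin(ac$k, ac$n - ac$k) / ac$n, 0)
  subset_sites(panel, miss < max_missing & maf >= min_maf)
}

# ---- VCF I/O --------------------------------------------------------------

#' Read a phased multi-sample VCF into a haplotype panel
#'
#' Biallelic SNP records are retained; multiallelic records and indels are
#' skipped with a reported count. The INFO `AA` tag, when present, populates
#' the per-site ancestral flag. A mixture of phased and unphased separators
#' marks the panel unphased (haplotype-based statistics will refuse it).
#'
#' @param path VCF file (v4.x, plain text or gzip).
#' @param pop_map Data frame with columns `individual` and `population`, or a
#'   path to a two-column TSV with those headers. Individuals present in the
#'   VCF but absent from the map are labelled `"unassigned"` with a warning.
#' @param chrom Chromosome to load; default = first chromosome in the file.
#' @return A [haplotype_panel()] with attribute `n_skipped` (records dropped
#'   as non-biallelic-SNP).
#' @export
read_vcf <- function(path, pop_map, chrom = NULL) {
  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(chrom)) chrom <- fix[1, "CHROM"]
  on_chrom <- fix[, "CHROM"] == chrom
  snp <- on_chrom &
    nchar(fix[, "REF"]) == 1L & fix[, "REF"] %in% c("A", "C", "G", "T") &
    nchar(fix[, "ALT"]) == 1L & fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(on_chrom & !snp)
  if (n_skipped)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  inds <- colnames(gt)
  ok <- grepl("^[01.][|/][01.]", gt) | is.na(gt)
  if (!all(ok))
    stop("malformed GT at record ", which(!ok, arr.ind = TRUE)[1, 1])
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  a1[a1 == "." | is.na(a1)] <- NA
  a2[a2 == "." | is.na(a2)] <- NA
  phased <- all(substr(gt[!is.na(gt)], 2, 2) == "|")

  nsite <- nrow(gt)
  haps <- matrix(NA_integer_, nsite, 2L * length(inds))
  haps[, seq(1, by = 2, length.out = length(inds))] <- suppressWarnings(as.integer(a1))
  haps[, seq(2, by = 2, length.out = length(inds))] <- suppressWarnings(as.integer(a2))

  pop <- pop_map$population[match(inds, pop_map$individual)]
  if (anyNA(pop)) {
    warning("individual(s) missing from pop_map labelled 'unassigned': ",
            paste(inds[is.na(pop)], collapse = ", "))
    pop[is.na(pop)] <- "unassigned"
  }

  aa <- vcfR::extract.info(v, element = "AA")[snp]
  anc <- rep(NA, nsite)
  if (!all(is.na(aa))) {
    anc[!is.na(aa) & aa == fix[, "REF"]] <- TRUE
    anc[!is.na(aa) & aa == fix[, "ALT"]] <- FALSE
  }

  p <- haplotype_panel(chrom = chrom, pos = as.numeric(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"], haps = haps,
                       individuals = inds, pop = pop,
                       ancestral_is_ref = anc, phased = phased)
  attr(p, "n_skipped") <- n_skipped
  p
}

#' Write a haplotype panel as VCF v4.2
#'
#' Emits plain-text VCF with GT fields and, where the ancestral state is
#' known, an `AA` INFO tag.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals), collapse = "\t")), con)
  if (!n_sites(panel)) return(invisible(path))
  sep <- if (panel$phased) "|" else "/"
  h <- panel$haps
  hc <- matrix(as.character(h), nrow(h), ncol(h))
  hc[is.na(hc)] <- "."
  odd <- seq(1, ncol(h), by = 2)
  gt <- matrix(paste(hc[, odd], hc[, odd + 1], sep = sep),
               nrow(h), length(odd))
  info <- ifelse(is.na(panel$ancestral_is_ref), ".",
                 paste0("AA=", ifelse(panel$ancestral_is_ref, panel$ref, panel$alt)))
  lines <- paste(panel$chrom, format(panel$pos, scientific = FALSE, trim = TRUE),
                 ".", panel$ref, panel$alt, ".", "PASS", info, "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a population map TSV (columns: individual, population)
#' @param path Two-column tab-separated file with a header line.
#' @return Data frame with columns `individual`, `population`.
#' @export
read_pop_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("individual", "population") %in% names(m)))
    stop("pop map needs columns 'individual' and 'population'")
  m
}

#' @rdname read_pop_map
#' @param pop_map Data frame as returned by [read_pop_map()].
#' @export
write_pop_map <- function(pop_map, path) {
  utils::write.table(pop_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- window grids ---------------------------------------------------------

#' Build a sliding window grid over a chromosome
#'
#' Windows anchor at position 0 and advance by `step`; the final window is
#' truncated at the chromosome end so every bp is covered. The canonical scan
#' geometry is a 50-kb window sliding by 25 kb.
#'
#' @param chrom_length Chromosome length in bp.
#' @param size Window size in bp.
#' @param step Stride in bp; must not exceed `size` (gaps would break
#'   coverage).
#' @param chrom Chromosome label carried in the grid.
#' @return A `window_grid` data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
make_windows <- function(chrom_length, size = 50000, step = 25000,
                         chrom = "1") {
  stopifnot(step > 0, size >= 1, chrom_length > 0)
  if (step > size) stop("step > size would leave uncovered gaps")
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  starts <- starts[starts < chrom_length]
  # keep windows that add coverage: start before the chromosome end and not
  # fully duplicating the final truncated span
  ends <- pmin(starts + size, chrom_length)
  keep <- c(TRUE, ends[-1] > ends[-length(ends)])
  g <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                  stringsAsFactors = FALSE)
  attr(g, "size") <- size
  attr(g, "step") <- step
  attr(g, "chrom_length") <- chrom_length
  class(g) <- c("window_grid", "data.frame")
  g
}

same_grid <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
    identical(a$end, b$end)
}

# sum per-site values over windows (sites at 0-based positions pos0, sorted)
window_sum <- function(values, pos0, grid) {
  cs <- c(0, cumsum(values))
  lo <- findInterval(grid$start - 0.5, pos0)
  hi <- findInterval(grid$end - 0.5, pos0)
  cs[hi + 1] - cs[lo + 1]
}

#' Write a window-statistic table as TSV
#' @param grid A `window_grid` (optionally with statistic columns).
#' @param path Output file.
#' @export
write_window_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- genetic maps ---------------------------------------------------------

#' Genetic map from anchor positions
#'
#' Piecewise-linear map from bp to cM. The default map is a flat
#' 1 cM per Mb, the recombination-rate convention used for the haplotype
#' scans.
#'
#' @param bp Anchor positions (bp), increasing.
#' @param cm Cumulative cM at the anchors, non-decreasing.
#' @param chrom Chromosome label.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(bp, cm, chrom = "1") {
  stopifnot(length(bp) == length(cm), length(bp) >= 1)
  if (is.unsorted(bp, strictly = TRUE)) stop("bp anchors must increase")
  if (any(diff(cm) < 0)) stop("cM must be non-decreasing in bp")
  structure(list(chrom = as.character(chrom), bp = as.numeric(bp),
                 cm = as.numeric(cm)),
            class = "genetic_map")
}

#' @rdname genetic_map
#' @param rate cM per Mb for a uniform map.
#' @export
default_genetic_map <- function(rate = 1, chrom = "1") {
  m <- genetic_map(bp = c(0, 1e6), cm = c(0, rate), chrom = chrom)
  attr(m, "uniform_rate") <- rate
  m
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between anchors; extrapolation beyond the terminal
#' anchors continues at the terminal interval's rate.
#'
#' @param map A [genetic_map()].
#' @param pos Physical positions (bp).
#' @return Genetic positions in cM.
#' @export
interpolate_cm <- function(map, pos) {
  stopifnot(all(pos >= 0))
  bp <- map$bp; cm <- map$cm
  if (length(bp) == 1) return(rep(cm, length(pos)))
  i <- findInterval(pos, bp, rightmost.closed = FALSE, all.inside = TRUE)
  rate <- (cm[i + 1] - cm[i]) / (bp[i + 1] - bp[i])
  cm[i] + rate * (pos - bp[i])
}

#' Read a genetic map TSV (columns: chrom, bp, cm)
#' @param path Tab-separated file with header `chrom`, `bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t")
  genetic_map(bp = m$bp, cm = m$cm, chrom = m$chrom[1])
}

# ---- interval sets --------------------------------------------------------

#' Generic genomic interval set (0-based half-open)
#'
#' The BED-convention carrier for sweeps, genes, QTLs and CNV regions.
#'
#' @param chrom Chromosome per record.
#' @param start,end 0-based half-open bounds; `start < end`, no negatives.
#' @param name,score Optional per-record annotation.
#' @return An `interval_set` data frame.
#' @export
interval_set <- function(chrom, start, end, name = ".", score = 0) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) && (any(start < 0) || any(start >= end)))
    stop("intervals need 0 <= start < end")
  s <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  name = rep_len(as.character(name), length(start)),
                  score = rep_len(as.numeric(score), length(start)),
                  stringsAsFactors = FALSE)
  class(s) <- c("interval_set", "data.frame")
  s
}

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

from_granges <- function(gr, name = ".", score = 0) {
  interval_set(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr), name = name, score = score)
}

#' Read / write BED3+ interval files
#'
#' BED columns chrom, start, end and optionally name, score; BED coordinates
#' are already 0-based half-open so records pass through unchanged.
#'
#' @param path BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  interval_set(chrom = b[[1]], start = b[[2]], end = b[[3]],
               name = if (ncol(b) >= 4) b[[4]] else ".",
               score = if (ncol(b) >= 5) b[[5]] else 0)
}

#' @rdname read_bed
#' @param x An [interval_set()].
#' @export
write_bed <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE), x$name,
               format(x$score, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' All pairs of overlapping intervals
#'
#' @param a,b [interval_set()]s in the same coordinate convention.
#' @param min_overlap Minimum overlap in bp (>= 1).
#' @return Data frame with indices `a_idx`, `b_idx` and the overlap width.
#' @export
intersect_intervals <- function(a, b, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  if (!nrow(a) || !nrow(b))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap = numeric()))
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      minoverlap = min_overlap)
  ai <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  data.frame(a_idx = ai, b_idx = bi, overlap = ov)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Intervals on the same chromosome that overlap or lie within `max_gap` bp
#' of each other are unioned; output is sorted and disjoint.
#'
#' @param a An [interval_set()].
#' @param max_gap Maximum gap (bp) bridged when merging.
#' @return An [interval_set()].
#' @export
merge_intervals <- function(a, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (!nrow(a)) return(a)
  gr <- GenomicRanges::reduce(as_granges(a), min.gapwidth = max_gap + 1)
  gr <- GenomicRanges::sort(gr)
  from_granges(gr)
}
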