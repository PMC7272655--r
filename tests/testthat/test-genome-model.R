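test_that("make_windows produces the canonical sliding grid", {
  g <- make_windows(100000, 50000, 25000)
  expect_equal(g$start, c(0, 25000, 50000))
  expect_equal(g$end, c(50000, 75000, 100000))

  g1 <- make_windows(40000, 50000, 25000)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$start, g1$end), c(0, 40000))

  g2 <- make_windows(100001, 50000, 25000)
  expect_equal(nrow(g2), 4)
  expect_equal(c(g2$start[4], g2$end[4]), c(75000, 100001))

  expect_error(make_windows(1e5, 25000, 50000), "gap")
})

test_that("sliding windows cover every base the expected number of times", {
  g <- make_windows(200000, 50000, 25000)
  bp <- seq(0, 199999, by = 500)
  cover <- vapply(bp, function(x) sum(g$start <= x & g$end > x), numeric(1))
  expect_true(all(cover >= 1))
  interior <- bp >= 25000 & bp < 175000
  expect_true(all(cover[interior] == 2)) # size / step = 2 except at edges
})

test_that("genetic map interpolation is linear with terminal extrapolation", {
  expect_equal(interpolate_cm(default_genetic_map(), 2e6), 2)
  m <- genetic_map(bp = c(0, 1e6), cm = c(0, 3))
  expect_equal(interpolate_cm(m, 5e5), 1.5)
  expect_equal(interpolate_cm(m, c(0, 1e6)), c(0, 3)) # anchors exact
  expect_equal(interpolate_cm(m, 2e6), 6)             # linear extrapolation
  expect_error(genetic_map(bp = c(0, 10), cm = c(1, 0)), "non-decreasing")
})

test_that("interval intersection honors half-open bounds and min_overlap", {
  a <- interval_set("1", 0, 100)
  b <- interval_set("1", 100, 200)
  expect_equal(nrow(intersect_intervals(a, b)), 0)
  b2 <- interval_set("1", 50, 150)
  expect_equal(nrow(intersect_intervals(a, b2, min_overlap = 50)), 1)
  expect_equal(nrow(intersect_intervals(a, b2, min_overlap = 51)), 0)
})

test_that("interval algebra matches an all-pairs brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 50
    s <- sample.int(10000, n)
    a <- interval_set(sample(c("1", "2"), n, TRUE), s, s + sample.int(500, n))
    s2 <- sample.int(10000, n)
    b <- interval_set(sample(c("1", "2"), n, TRUE), s2, s2 + sample.int(500, n))
    got <- intersect_intervals(a, b)
    want <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (a$chrom[i] == b$chrom[j] &&
          min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1)
        want <- want + 1
    }
    expect_equal(nrow(got), want)
  }
})

test_that("merge_intervals equals a brute-force union and respects max_gap", {
  m <- merge_intervals(interval_set("1", c(0, 25000), c(50000, 75000)))
  expect_equal(c(m$start, m$end), c(0, 75000))

  d <- interval_set("1", c(0, 300), c(100, 400))
  expect_equal(nrow(merge_intervals(d, max_gap = 100)), 2)
  expect_equal(nrow(merge_intervals(d, max_gap = 200)), 1)

  set.seed(1)
  s <- sample.int(5000, 10)
  iv <- interval_set("1", s, s + sample.int(800, 10))
  got <- merge_intervals(iv, 0)
  covered <- rep(FALSE, 6000)
  for (i in 1:10) covered[(iv$start[i] + 1):iv$end[i]] <- TRUE
  runs <- rle(covered)
  expect_equal(nrow(got), sum(runs$values))
  expect_equal(sum(got$end - got$start), sum(covered))
})

test_that("BED and window TSV round-trip bit-identically", {
  iv <- interval_set(c("1", "2"), c(0, 1234), c(999, 5678),
                     name = c("a", "b"), score = c(1, 2.5))
  f <- tempfile(fileext = ".bed")
  write_bed(iv, f)
  back <- read_bed(f)
  expect_identical(as.data.frame(back), as.data.frame(iv))

  g <- make_windows(1e5)
  g$stat <- c(1.5, 2.5, NA)
  f2 <- tempfile(fileext = ".tsv")
  write_window_tsv(g, f2)
  back2 <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_identical(back2$stat, g$stat)
  expect_identical(back2$start, as.integer(g$start))
})

test_that("VCF reading maps GT, AA tags and skips non-biallelic records", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1\t0|0",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0|1\t0|2\t0|0",
    "1\t300\t.\tG\tC\t.\tPASS\tAA=C\tGT\t./.\t0|1\t1|1"), f)
  pm <- data.frame(individual = c("s1", "s2"), population = c("w", "d"))
  expect_warning(
    expect_message(p <- read_vcf(f, pm), "skipped 1"),
    "unassigned")
  expect_equal(length(p$pos), 2)           # triallelic record dropped
  expect_equal(attr(p, "n_skipped"), 1)
  expect_equal(p$pos, c(100, 300))
  expect_true(p$ancestral_is_ref[1])       # AA = REF
  expect_false(p$ancestral_is_ref[2])      # AA = ALT
  expect_true(all(is.na(p$haps[2, 1:2])))  # ./. -> both haplotypes missing
  expect_equal(p$haps[1, ], c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(as.character(p$pop), c("w", "d", "unassigned"))
  expect_true(p$phased)
})

test_that("VCF writing round-trips a simulated panel", {
  sim <- small_split_sim()
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$panel, f)
  pm <- data.frame(individual = sim$panel$individuals,
                   population = as.character(sim$panel$pop))
  back <- read_vcf(f, pm)
  expect_equal(back$pos, sim$panel$pos)
  expect_equal(unname(back$haps), unname(sim$panel$haps))
  expect_equal(back$ancestral_is_ref, sim$panel$ancestral_is_ref)
  expect_equal(as.character(back$pop), as.character(sim$panel$pop))
})

test_that("variant filtering applies the missingness and MAF rules", {
  # site 1: 2/10 alleles missing (>= 0.1) -> removed
  # site 2: MAF exactly 0.05 boundary (1/20... use 10 alleles: k=1 -> 0.1)
  haps <- rbind(c(0, 1, 0, 1, 0, 1, 0, 1, NA, NA),
                c(rep(0, 9), 1),
                c(rep(0, 10)))
  p <- haplotype_panel("1", c(10, 20, 30), rep("A", 3), rep("C", 3), haps,
                       paste0("i", 1:5), rep("x", 5))
  out <- filter_variants(p, max_missing = 0.1, min_maf = 0.1)
  expect_equal(out$pos, 20) # boundary MAF 0.1 retained, missing site dropped

  # 3-site toy, MAF 0.02 / 0.30 / 0.50 in 50 alleles, defaults -> 2 survive
  k <- c(1, 15, 25)
  haps2 <- t(sapply(k, function(x) sample(c(rep(1, x), rep(0, 50 - x)))))
  p2 <- haplotype_panel("1", c(1, 2, 3) * 10, rep("A", 3), rep("C", 3),
                        haps2, paste0("i", 1:25), rep("x", 25))
  expect_equal(length(filter_variants(p2)$pos), 2)

  empty <- filter_variants(filter_variants(p2, 0.1, 0.5), 0.1, 0.5)
  expect_equal(length(empty$pos), 1) # idempotent on the surviving 0.5-MAF site
  none <- filter_variants(haplotype_panel("1", numeric(), character(),
                                          character(),
                                          matrix(0L, 0, 50),
                                          paste0("i", 1:25), rep("x", 25)))
  expect_equal(length(none$pos), 0)  # empty panel passes through
})

test_that("panel construction validates its invariants", {
  expect_error(haplotype_panel("1", c(10, 5), "A", "C",
                               matrix(0L, 2, 2), "i1", "x"),
               "increasing")
  expect_error(haplotype_panel("1", 10, "A", "C", matrix(2L, 1, 2),
                               "i1", "x"), "0, 1 or NA")
  expect_error(haplotype_panel("1", 10, "A", "C", matrix(0L, 1, 4),
                               "i1", "x"), "2 columns")
})

test_that("CNV matrix TSV round-trips", {
  cnv <- simulate_cnv_matrix(n_per_pop = c(a = 3, b = 3), n_regions = 4,
                             delta_freq = 0.5, sigma = 0.1, seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_cnv_matrix(cnv, f)
  back <- read_cnv_matrix(f)
  expect_equal(unname(back$depth), unname(cnv$depth), tolerance = 1e-12)
  expect_equal(back$regions$start, cnv$regions$start)
  expect_equal(as.character(back$pop), as.character(cnv$pop))
})
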