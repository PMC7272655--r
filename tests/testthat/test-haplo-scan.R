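test_that("EHH counts distinct extended haplotypes among carriers", {
  # identical carriers: EHH stays 1
  h <- matrix(1L, 5, 4)
  expect_true(all(ehh(h, 3, "right")$ehh == 1))

  # 4 carriers splitting 2/2 at the first flanking site: (1 + 1) / 6
  h2 <- matrix(0L, 2, 4)
  h2[2, ] <- c(0L, 0L, 1L, 1L)
  expect_equal(ehh(h2, 1, "right")$ehh, c(1, 2 / 6))

  # two carriers differing at the first site: EHH drops to 0
  h3 <- matrix(c(1L, 1L, 0L, 1L), 2, 2, byrow = TRUE)
  expect_equal(ehh(h3, 1, "right")$ehh[2], 0)

  expect_error(ehh(matrix(NA_integer_, 2, 3), 1, "left"), "fully called")
})

test_that("EHH is non-increasing outward and within [0, 1]", {
  set.seed(21)
  for (i in 1:10) {
    h <- matrix(rbinom(30 * 8, 1, 0.5), 30, 8)
    for (side in c("left", "right")) {
      e <- ehh(h, 15, side)$ehh
      expect_true(all(diff(e) <= 1e-12))
      expect_true(all(e >= 0 & e <= 1))
    }
  }
})

test_that("iHH trapezoid integration truncates at the cutoff", {
  # EHH = 1 over exactly 0.1 cM, curve ends there: rectangle of area 0.1
  r <- ihh(c(1, 1, 1), cm = c(0, 0.05, 0.1), cutoff = 0.05)
  expect_equal(r$ihh, 0.1)
  expect_equal(r$flag, 1L) # ran off the data still above the cutoff

  # curve dives below the cutoff immediately: one small trapezoid
  r2 <- ihh(c(1, 0.01), cm = c(0, 0.02))
  expect_equal(r2$ihh, 0.5 * (1 + 0.01) * 0.02)
  expect_equal(r2$flag, 0L)

  # piecewise-linear toy equals the hand trapezoid sum up to the crossing
  e <- c(1, 0.8, 0.5, 0.2, 0.04, 0.5)
  cm <- c(0, 0.01, 0.02, 0.04, 0.05, 0.06)
  want <- 0.5 * sum((e[1:4] + e[2:5]) * diff(cm[1:5]))
  expect_equal(ihh(e, cm)$ihh, want)

  # gap and extent rules flag and truncate
  r3 <- ihh(c(1, 1, 1), cm = c(0, 0.01, 0.5), bp = c(0, 1e4, 5e5),
            max_gap = 2e5)
  expect_equal(r3$flag, 2L)
  expect_equal(r3$ihh, 0.5 * 2 * 0.01)
  expect_error(ihh(c(0.5, 0.4), cm = c(0, 1)), "start at 1")
})

test_that("single-site iHS agrees between the R and compiled paths", {
  sim <- small_neutral_sim()
  panel <- sim$panel
  res <- ihs_scan(panel, "wild")
  ok <- which(res$flag == "ok")[1:5]
  for (i in ok) {
    r <- ihs_unstandardized(panel, "wild", res$pos[i])
    expect_equal(r$ihh_a, res$ihh_a[i], tolerance = 1e-12)
    expect_equal(r$ihh_d, res$ihh_d[i], tolerance = 1e-12)
    expect_equal(r$uihs, res$uihs[i], tolerance = 1e-12)
  }
})

test_that("iHS sign convention and symmetry", {
  # symmetric haplotype structure around both alleles: ratio 1, iHS 0
  h <- rbind(rep(0L, 8),
             rep(c(0L, 1L), 4),
             rep(c(0L, 1L), 4),
             rep(0L, 8))
  p <- haplotype_panel("1", c(100, 5000, 10000, 15000), rep("A", 4),
                       rep("C", 4), h, paste0("i", 1:4), rep("x", 4),
                       ancestral_is_ref = rep(TRUE, 4))
  r <- ihs_unstandardized(p, "x", 5000, min_carriers = 2)
  expect_equal(r$uihs, 0)

  # derived allele on one long identical block, ancestral fragmented
  set.seed(14)
  n_sites <- 41
  hap <- matrix(rbinom(n_sites * 12, 1, 0.5), n_sites, 12)
  core <- 21
  hap[core, ] <- c(rep(1L, 6), rep(0L, 6))
  hap[, 1:6] <- hap[, 1] # derived carriers identical everywhere
  hap[core, ] <- c(rep(1L, 6), rep(0L, 6))
  p2 <- haplotype_panel("1", seq_len(n_sites) * 500, rep("A", n_sites),
                        rep("C", n_sites), hap, paste0("i", 1:6),
                        rep("x", 6), ancestral_is_ref = rep(TRUE, n_sites))
  r2 <- ihs_unstandardized(p2, "x", core * 500)
  expect_lt(r2$uihs, 0)
})

test_that("iHS is invariant to relabeling individuals", {
  sim <- small_neutral_sim()
  panel <- sim$panel
  res1 <- ihs_scan(panel, "wild")
  perm <- sample(seq_along(panel$individuals))
  cols <- as.vector(rbind(2 * perm - 1, 2 * perm))
  panel2 <- panel
  panel2$haps <- panel$haps[, cols]
  panel2$individuals <- panel$individuals[perm]
  panel2$pop <- panel$pop[perm]
  res2 <- ihs_scan(panel2, "wild")
  expect_equal(res1$uihs, res2$uihs)
})

test_that("standardization centers and scales within frequency bins", {
  sim <- small_neutral_sim()
  res <- standardize_ihs(ihs_scan(sim$panel, "wild"), n_bins = 10,
                         min_bin = 10)
  ok <- !is.na(res$ihs)
  for (b in unique(res$bin[ok])) {
    sel <- ok & res$bin == b
    expect_equal(mean(res$ihs[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(res$ihs[sel]), 1, tolerance = 1e-9)
  }

  # single bin reduces to a global z-score
  res1 <- standardize_ihs(ihs_scan(sim$panel, "wild"), n_bins = 1)
  ok1 <- !is.na(res1$ihs)
  z <- scale(res1$uihs[ok1])
  expect_equal(res1$ihs[ok1], as.numeric(z), tolerance = 1e-9)

  # two-bin toy with known means and sds
  toy <- data.frame(pos = 1:8, daf = c(rep(0.2, 4), rep(0.8, 4)),
                    ihh_a = 1, ihh_d = 1,
                    uihs = c(1, 2, 3, 4, 10, 20, 30, 40), flag = "ok")
  out <- standardize_ihs(toy, n_bins = 2, min_bin = 2)
  expect_equal(out$ihs[1:4], (c(1, 2, 3, 4) - 2.5) / sd(1:4))
  expect_equal(out$ihs[5:8], (c(10, 20, 30, 40) - 25) / sd(c(10, 20, 30, 40)))
})

test_that("window summary flags the top tail of extreme-score proportions", {
  g <- make_windows(100 * 25000, 25000, 25000)
  # 100 windows x 20 scored SNPs; five windows carry extreme scores
  pos <- rep(g$start, each = 20) + seq(100, 24000, length.out = 20)
  ihs <- rep(0.5, length(pos))
  hot <- c(10, 30, 50, 70, 90)
  for (w in hot) ihs[(w - 1) * 20 + 1:8] <- 3
  res <- data.frame(pos = pos + 1, ihs = ihs)
  out <- ihs_window_summary(res, g, min_scored = 5)
  expect_equal(which(out$significant), hot)

  # all sub-threshold scores: nothing flagged under the degenerate rule
  res0 <- data.frame(pos = pos + 1, ihs = rep(0.3, length(pos)))
  out0 <- suppressWarnings(ihs_window_summary(res0, g, min_scored = 5))
  expect_true(all(out0$prop_extreme == 0))
  expect_false(any(out0$significant))
})
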