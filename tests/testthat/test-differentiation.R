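test_that("Weir-Cockerham site F_ST matches fixed-difference expectations", {
  expect_equal(wc_fst_site(c(10, 0), c(10, 10))$fst, 1)
  same <- wc_fst_site(c(3, 3), c(10, 10))
  expect_lte(same$fst, 0)
  expect_true(is.na(wc_fst_site(c(0, 0), c(10, 10))$fst)) # no variance
  expect_error(wc_fst_site(3, 10), ">= 2 populations")
})

test_that("Weir-Cockerham components match the ANOVA oracle", {
  got <- wc_fst_site(c(3, 7), c(10, 10))
  want <- oracle_wc_fst(c(3, 7), c(10, 10))
  expect_equal(got$a, want$a, tolerance = 1e-10)
  expect_equal(got$b, want$b, tolerance = 1e-10)
  expect_equal(got$fst, want$fst, tolerance = 1e-10)

  set.seed(9)
  for (i in 1:200) {
    r <- sample(2:4, 1)
    n <- sample(4:30, r, replace = TRUE)
    k <- vapply(n, function(x) sample(0:x, 1), numeric(1))
    if (sum(k) == 0 || sum(k) == sum(n)) next
    got <- wc_fst_site(k, n)
    want <- oracle_wc_fst(k, n)
    expect_equal(got$fst, want$fst, tolerance = 1e-10)
  }
})

test_that("windowed F_ST pools sites in both modes", {
  sites <- data.frame(pos = c(100, 200, 300),
                      a = c(1, 0, 0.5), b = c(0, 1, 0.5), c = 0)
  sites$fst <- sites$a / (sites$a + sites$b + sites$c)
  g <- make_windows(1000, 1000, 1000)
  expect_equal(window_fst(sites, g, "mean")$fst, mean(c(1, 0, 0.5)))
  expect_equal(window_fst(sites, g, "ratio")$fst, 1.5 / 3)

  sim <- small_split_sim()
  g2 <- make_windows(3e5)
  ws <- sweepscan:::wc_fst_sites(sim$panel)
  for (mode in c("mean", "ratio")) {
    out <- window_fst(ws, g2, mode)
    w <- 5
    sel <- ws$pos - 1 >= g2$start[w] & ws$pos - 1 < g2$end[w] & !is.na(ws$fst)
    want <- if (mode == "mean") mean(ws$fst[sel]) else
      sum(ws$a[sel]) / sum(ws$a[sel] + ws$b[sel] + ws$c[sel])
    expect_equal(out$fst[w], want)
  }
})

test_that("V_ST matches hand computation, masks and clips", {
  expect_equal(vst(c(rep(1, 5), rep(0, 5)), rep(c("a", "b"), each = 5)), 1)
  expect_true(is.na(vst(rep(0.7, 10), rep(c("a", "b"), each = 5))))
  x1 <- c(0.9, 1.1, 1.0); x2 <- c(0.4, 0.6, 0.5)
  expect_equal(vst(c(x1, x2), rep(c("a", "b"), each = 3)),
               oracle_vst(x1, x2))
  set.seed(2)
  for (i in 1:50) {
    x1 <- rnorm(sample(2:8, 1)); x2 <- rnorm(sample(2:8, 1))
    v <- vst(c(x1, x2), rep(c("a", "b"), c(length(x1), length(x2))))
    expect_equal(v, oracle_vst(x1, x2))
    expect_true(is.na(v) || (v >= 0 && v <= 1))
    # location/scale invariance
    v2 <- vst(3 + 2 * c(x1, x2), rep(c("a", "b"), c(length(x1), length(x2))))
    expect_equal(v, v2)
  }
})

test_that("Reynolds distance follows the ratio-of-sums coancestry form", {
  f <- rbind(a = c(0.2, 0.8), b = c(0.2, 0.8))
  expect_equal(reynolds_distance(f)["a", "b"], 0)
  f2 <- rbind(a = 1, b = 0)
  expect_equal(reynolds_distance(f2)["a", "b"], Inf) # theta = 1
  set.seed(5)
  p1 <- runif(10); p2 <- runif(10)
  expect_equal(reynolds_distance(rbind(x = p1, y = p2))["x", "y"],
               oracle_reynolds(p1, p2))
})

test_that("p-distance counts allele-sharing mismatches", {
  p <- toy_panel(seed = 8, n_sites = 10)
  D <- p_distance_matrix(p)
  expect_true(all(diag(D) == 0))
  dos <- sweepscan:::dosage_matrix(p)
  expect_equal(D[1, 3], mean(abs(dos[, 1] - dos[, 3]) / 2))
  # identical individuals at distance zero
  p$haps[, 3:4] <- p$haps[, 1:2]
  expect_equal(p_distance_matrix(p)[1, 2], 0)
})

test_that("neighbor joining reconstructs additive matrices exactly", {
  set.seed(31)
  # 4-taxon quartet with known split
  tr <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.5,D:3):1);")
  d <- cophenetic(ape::unroot(tr))
  est <- nj_tree(d)
  expect_equal(cophenetic(est)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(ape::dist.topo(est, ape::unroot(tr)), 0,
               ignore_attr = TRUE)

  # three taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 3)))

  # random additive matrices, exact recovery, cross-checked against ape
  for (i in 1:25) {
    ra <- random_additive_matrix(sample(4:12, 1))
    est <- nj_tree(ra$d)
    expect_equal(cophenetic(est)[rownames(ra$d), colnames(ra$d)], ra$d,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(est, ape::nj(ra$d)), 0, ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3")
})

test_that("bootstrap supports hit 100 for clean two-cluster structure", {
  set.seed(12)
  # two diverged pairs: the single non-trivial bipartition is backed by
  # half the sites, so every bootstrap replicate recovers it
  n_sites <- 120
  haps <- cbind(matrix(0L, n_sites, 4), matrix(1L, n_sites, 4))
  haps[1:(n_sites / 2), ] <- 1L - haps[1:(n_sites / 2), ]
  noise <- matrix(rbinom(length(haps), 1, 0.02), nrow(haps))
  haps <- (haps + noise) %% 2L
  p <- haplotype_panel("1", seq_len(n_sites) * 10, rep("A", n_sites),
                       rep("C", n_sites), haps, paste0("i", 1:4),
                       rep(c("a", "b"), each = 2))
  tr <- bootstrap_support(p, n_reps = 30, distance = "p", seed = 2)
  expect_true(all(tr$node.label == 100))

  tr1 <- bootstrap_support(p, n_reps = 1, distance = "p", seed = 3)
  expect_true(all(tr1$node.label %in% c(0, 100)))

  tr2a <- bootstrap_support(p, n_reps = 10, distance = "p", seed = 9)
  tr2b <- bootstrap_support(p, n_reps = 10, distance = "p", seed = 9)
  expect_identical(ape::write.tree(tr2a), ape::write.tree(tr2b))
})
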