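test_that("identical parameters give byte-identical simulations", {
  p <- sim_params(N_anc = 30, N_wild = 30, N_dom = 30, L = 1e5, mu = 1e-6,
                  rec = 1e-7, T_split = 20, burn_in = 150,
                  n_sample_wild = 6, n_sample_dom = 6, seed = 5)
  a <- simulate_panel(p)
  b <- simulate_panel(p)
  expect_identical(a$panel$pos, b$panel$pos)
  expect_identical(a$panel$haps, b$panel$haps)
  expect_identical(a$outgroup, b$outgroup)
})

test_that("zero mutation rate yields no segregating sites", {
  p <- sim_params(N_anc = 20, N_wild = 20, N_dom = 20, L = 1e5, mu = 0,
                  rec = 1e-7, T_split = 10, burn_in = 50, T_outgroup = 0,
                  n_sample_wild = 5, n_sample_dom = 5, seed = 1)
  sim <- simulate_panel(p)
  expect_equal(length(sim$panel$pos), 0)
})

test_that("neutral diversity matches the coalescent expectation 4 N mu", {
  pis <- numeric(6)
  for (i in 1:6) {
    sim <- simulate_panel(sim_params(N_anc = 50, N_wild = 50, N_dom = 50,
                                     L = 2e5, mu = 1e-6, rec = 1e-7,
                                     T_split = 0, burn_in = 500,
                                     n_sample_wild = 12, n_sample_dom = 12,
                                     seed = 50 + i))
    H <- sim$panel$haps
    k <- rowSums(H); n <- ncol(H)
    pis[i] <- sum(2 * k * (n - k) / (n * (n - 1))) / 2e5
  }
  theta <- 4 * 50 * 1e-6
  expect_lt(abs(mean(pis) - theta) / (sd(pis) / sqrt(6)), 3)
})

test_that("the folded SFS matches the neutral 1/i + 1/(n-i) shape", {
  # recombination is raised so the pooled sites represent many independent
  # genealogies; with tight linkage the chi-square would be overdispersed
  pooled <- 0
  for (i in 1:10) {
    sim <- simulate_panel(sim_params(N_anc = 50, N_wild = 50, N_dom = 50,
                                     L = 1e5, mu = 1e-6, rec = 2e-6,
                                     T_split = 0, burn_in = 500,
                                     n_sample_wild = 10, n_sample_dom = 5,
                                     seed = 60 + i))
    pooled <- pooled + folded_sfs(sim$panel, "wild", n_project = 20)
  }
  # wild sample = 20 haplotypes; folded classes 1..10
  m <- 20
  i <- 1:10
  expec <- (1 / i + 1 / (m - i)) / (1 + (i == m - i))
  expec <- expec / sum(expec) * sum(pooled)
  chi2 <- sum((pooled - expec)^2 / expec)
  expect_gt(pchisq(chi2, df = length(i) - 1, lower.tail = FALSE), 0.001)
})

test_that("a planted sweep depresses local diversity", {
  wins <- 0
  for (i in 1:8) {
    sim <- simulate_panel(sim_params(
      N_anc = 60, N_wild = 60, N_dom = 60, L = 4e5, mu = 1e-6, rec = 1e-7,
      T_split = 60, burn_in = 600, n_sample_wild = 10, n_sample_dom = 12,
      sweep = list(pos = 2e5, s = 0.2, start = 5, min_freq = 0.95,
                   max_attempts = 300),
      seed = 90 + i))
    g <- make_windows(4e5)
    pd <- window_pi(sim$panel, g, "domestic")
    truth_w <- which(g$start <= sim$sweep$pos & g$end > sim$sweep$pos)
    wins <- wins + (min(pd$pi[truth_w]) < stats::median(pd$pi))
  }
  expect_gte(wins, 7)
})

test_that("sweep conditioning errors out when the retry budget is exhausted", {
  p <- sim_params(N_anc = 30, N_wild = 30, N_dom = 30, L = 1e5, mu = 1e-6,
                  rec = 1e-7, T_split = 20, burn_in = 100,
                  n_sample_wild = 5, n_sample_dom = 5,
                  sweep = list(pos = 5e4, s = 0.01, start = 18,
                               min_freq = 0.95, max_attempts = 2),
                  seed = 2)
  expect_error(simulate_panel(p), "2 attempts")
})

test_that("simulated CNV matrices span the V_ST range", {
  cnv0 <- simulate_cnv_matrix(c(wild = 20, domestic = 20), n_regions = 40,
                              delta_freq = 0, sigma = 0.1, seed = 3)
  v0 <- vst_scan(cnv0)$vst
  expect_lt(mean(v0, na.rm = TRUE), 0.1)

  cnv1 <- simulate_cnv_matrix(c(wild = 20, domestic = 20), n_regions = 5,
                              delta_freq = 1, sigma = 1e-3, seed = 4)
  expect_true(all(vst_scan(cnv1)$vst > 0.99))

  # intermediate differentiation against a Monte-Carlo oracle
  set.seed(9)
  oracle <- mean(replicate(3000, {
    cw <- rbinom(20, 2, 0.25); cd <- rbinom(20, 2, 0.75)
    oracle_vst(cw / 2 + rnorm(20, 0, 0.1), cd / 2 + rnorm(20, 0, 0.1))
  }), na.rm = TRUE)
  vs <- unlist(lapply(1:12, function(i)
    vst_scan(simulate_cnv_matrix(c(wild = 20, domestic = 20), n_regions = 25,
                                 delta_freq = 0.5, sigma = 0.1,
                                 seed = 100 + i))$vst))
  expect_lt(abs(mean(vs, na.rm = TRUE) - oracle),
            3 * sd(vs, na.rm = TRUE) / sqrt(sum(!is.na(vs))))
})

test_that("QTL placement honors enrichment near truth sweeps", {
  truth <- interval_set("1", 480000, 520000)
  q1 <- simulate_qtl_intervals(1e6, n = 20, length_dist = c(3e4, 5e3),
                               enrichment = 1, truth = truth, d = 0, seed = 5)
  ov <- intersect_intervals(q1, truth)
  expect_equal(length(unique(ov$a_idx)), 20)

  # uniform placement: overlap count near the analytic expectation
  hits <- n_tot <- 0
  for (s in 1:30) {
    q0 <- simulate_qtl_intervals(1e6, n = 20, length_dist = c(3e4, 1e3),
                                 enrichment = 0, seed = s)
    hits <- hits + length(unique(intersect_intervals(q0, truth)$a_idx))
    n_tot <- n_tot + 20
  }
  # P(overlap) for a 30-kb interval vs a 40-kb target on 1 Mb ~ (40+30)/970
  p_exp <- (40000 + 30000 - 1) / (1e6 - 30000)
  se <- sqrt(n_tot * p_exp * (1 - p_exp))
  expect_lt(abs(hits - n_tot * p_exp), 4 * se)

  expect_error(simulate_qtl_intervals(1e6, n = 0), "n >= 1")
  expect_error(simulate_qtl_intervals(1e6, n = 3, enrichment = 0.5),
               "truth")
})

test_that("simulation bundles write standard formats", {
  sim <- small_split_sim()
  dir <- tempfile()
  write_sim_result(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("panel.vcf",
                                               "truth_sweeps.bed",
                                               "pop_map.tsv",
                                               "params.json")))))
  prm <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(prm$L, 3e5)
})
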