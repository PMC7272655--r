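# Shared simulated fixtures, built once per test run and memoised.

.sim_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small two-population panel with modest divergence (fast; ~1 s)
small_split_sim <- function() memo("small_split", {
  simulate_panel(sim_params(N_anc = 60, N_wild = 60, N_dom = 60, L = 3e5,
                            mu = 1e-6, rec = 1e-7, T_split = 40,
                            burn_in = 600, T_outgroup = 1200,
                            n_sample_wild = 12, n_sample_dom = 12,
                            seed = 7))
})

# single-deme neutral panel (T_split = 0)
small_neutral_sim <- function() memo("small_neutral", {
  simulate_panel(sim_params(N_anc = 60, N_wild = 60, N_dom = 60, L = 3e5,
                            mu = 1e-6, rec = 1e-7, T_split = 0,
                            burn_in = 600, n_sample_wild = 12,
                            n_sample_dom = 12, seed = 11))
})

# hand-built tiny panel: 12 sites, 8 haplotypes (4 individuals, 2 pops)
toy_panel <- function(seed = 3, n_sites = 12, n_ind = 4, missing = 0) {
  set.seed(seed)
  haps <- matrix(rbinom(n_sites * 2 * n_ind, 1, runif(n_sites, 0.2, 0.8)),
                 n_sites, 2 * n_ind)
  if (missing > 0)
    haps[sample(length(haps), missing)] <- NA
  haplotype_panel(chrom = "1",
                  pos = sort(sample.int(10000, n_sites)),
                  ref = rep("A", n_sites), alt = rep("G", n_sites),
                  haps = haps,
                  individuals = paste0("ind", seq_len(n_ind)),
                  pop = rep(c("p1", "p2"), each = n_ind / 2),
                  ancestral_is_ref = rep(TRUE, n_sites))
}
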