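# Wright-Fisher forward simulation: phased two-population panels with an
# optional hard sweep, outgroup divergence, CNV intensity matrices and QTL
# intervals. The generation loop itself is compiled (src/); this file owns
# parameter handling, seeding, conditioning and panel assembly.

#' Simulation parameters
#'
#' Diploid Wright-Fisher model with discrete generations: an ancestral
#' population of `N_anc` diploids is burned in, then splits into a "wild"
#' and a "domestic" population that evolve separately for `T_split`
#' generations. Genic selection (fitness 1, 1+s, 1+2s) can drive a new
#' mutation through the domestic population; the run is conditioned on the
#' beneficial allele reaching `sweep$min_freq` by sampling time, retried
#' from the introduction generation up to `sweep$max_attempts` times.
#' Outgroup divergence is added as Poisson(2 mu T_outgroup L) substitutions
#' on the ancestral sequence.
#'
#' Defaults follow the organism-scale rates (mutation 2.5e-8 per bp per
#' generation; recombination 1e-8, i.e. 1 cM/Mb). [sim_params_desk()] gives
#' the rescaled desk-scale preset used throughout the package's calibration
#' experiments.
#'
#' @param N_anc,N_wild,N_dom Diploid population sizes (>= 2).
#' @param L Sequence length, bp.
#' @param mu Mutation rate per bp per generation.
#' @param rec Recombination rate per bp per generation (single crossover per
#'   meiosis with probability `rec * L`).
#' @param T_split Generations since the wild/domestic split (0 = sample both
#'   panels from the burned-in deme).
#' @param burn_in Burn-in generations for the ancestral population; default
#'   `10 * N_anc`.
#' @param sweep `NULL` for neutral runs, else a list with elements `pos`
#'   (bp), `s` (selection coefficient), `start` (generation after the split
#'   at which the mutation appears), and optionally `min_freq` (default
#'   0.95) and `max_attempts` (default 100).
#' @param T_outgroup Outgroup divergence time, generations (both branches
#'   combined via the factor 2 in the substitution rate).
#' @param n_sample_wild,n_sample_dom Individuals sampled per population.
#' @param seed Integer seed; identical parameters give identical output.
#' @param max_budget Guard on total haplotype-generations simulated.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(N_anc = 200, N_wild = 200, N_dom = 200, L = 2e6,
                       mu = 2.5e-8, rec = 1e-8, T_split = 400,
                       burn_in = 10 * N_anc, sweep = NULL, T_outgroup = 2000,
                       n_sample_wild = 25, n_sample_dom = 30, seed = 1,
                       max_budget = 5e7) {
  stopifnot(N_anc >= 2, N_wild >= 2, N_dom >= 2, L > 0, mu >= 0, rec >= 0,
            T_split >= 0, burn_in >= 0, T_outgroup >= 0)
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), !is.null(sweep$pos), !is.null(sweep$s),
              !is.null(sweep$start))
    stopifnot(sweep$pos >= 0, sweep$pos < L, sweep$s >= 0, sweep$s <= 1,
              sweep$start >= 1, sweep$start <= T_split)
    if (is.null(sweep$min_freq)) sweep$min_freq <- 0.95
    if (is.null(sweep$max_attempts)) sweep$max_attempts <- 100
  }
  cost <- 2 * N_anc * burn_in + 2 * (N_wild + N_dom) * T_split
  if (cost > max_budget)
    stop("simulation budget exceeded: ", cost, " haplotype-generations ",
         "(limit ", max_budget, "); reduce N, T or burn_in, or raise max_budget")
  structure(list(N_anc = N_anc, N_wild = N_wild, N_dom = N_dom, L = L,
                 mu = mu, rec = rec, T_split = T_split, burn_in = burn_in,
                 sweep = sweep, T_outgroup = T_outgroup,
                 n_sample_wild = n_sample_wild, n_sample_dom = n_sample_dom,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Desk-scale simulation preset
#'
#' N = 200 diploids per population, L = 2 Mb. Rates are calibrated so the
#' rescaled model reproduces the organism-scale observables the scan
#' statistics actually see: mutation 1e-6 gives per-bp diversity
#' theta = 4 N mu = 8e-4 (sheep-like); recombination 1e-7 gives an LD
#' half-decay of 1/(4 N rec) = 12.5 kb (the landrace scale) while keeping
#' within-sweep recombination escape low enough that a completed sweep
#' clears its 50-kb windows, as real sheep sweeps do; T_split = 100
#' generations puts the wild/domestic divergence at T/2N = 0.25 (window
#' F_ST ~ 0.2, the wild/landrace contrast) — deeper splits at this small N
#' let neutral haplotype blocks drift to fixation and mimic sweeps. The
#' optional sweep starts at generation 5 after the split — selection from
#' domestication onward — and completes close to sampling time.
#'
#' @param seed Integer seed.
#' @param sweep_s Selection coefficient; `NULL` or 0 for a neutral run.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_desk <- function(seed = 1, sweep_s = NULL, ...) {
  sweep <- NULL
  if (!is.null(sweep_s) && sweep_s > 0)
    sweep <- list(pos = 1e6, s = sweep_s, start = 5, min_freq = 0.95,
                  max_attempts = 300)
  sim_params(N_anc = 200, N_wild = 200, N_dom = 200, L = 2e6,
             mu = 1e-6, rec = 1e-7, T_split = 100, sweep = sweep,
             seed = seed, ...)
}

#' Simulate a phased two-population haplotype panel
#'
#' Runs the forward model of [sim_params()] and assembles a
#' [haplotype_panel()] for the sampled individuals (populations `"wild"` and
#' `"domestic"`), the per-site outgroup allele, and the true sweep location
#' as an [interval_set()]. Reference alleles are the simulated ancestral
#' states, so `ancestral_is_ref` is `TRUE` at every site. Outgroup
#' substitution sites enter the panel as records monomorphic in the ingroup
#' whose outgroup allele differs.
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_result` with elements `panel`, `truth`
#'   (interval set of planted sweep sites), `outgroup` (0 = ref, 1 = alt per
#'   panel site), `sweep` (list: attempts, final_freq, pos) and `params`.
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  sw <- params$sweep
  res <- wf_sim_cpp(params$N_anc, params$N_wild, params$N_dom, params$L,
                    params$mu, params$rec, params$burn_in, params$T_split,
                    if (is.null(sw)) -1 else sw$pos,
                    if (is.null(sw)) 0 else sw$s,
                    if (is.null(sw)) 0 else sw$start,
                    if (is.null(sw)) 0 else sw$min_freq,
                    if (is.null(sw)) 0 else sw$max_attempts,
                    params$n_sample_wild, params$n_sample_dom)

  pos0 <- res$pos                     # 0-based bp from the simulator
  haps <- res$haps
  outg <- rep(0L, length(pos0))       # outgroup carries the ancestral allele

  # outgroup divergence: substitutions since the outgroup split, placed as
  # ingroup-monomorphic sites where the outgroup allele is derived
  n_div <- stats::rpois(1, 2 * params$mu * params$T_outgroup * params$L)
  if (n_div > 0) {
    dpos <- sample.int(params$L, min(n_div, params$L)) - 1
    dpos <- setdiff(dpos, pos0)
    all_pos <- c(pos0, dpos)
    ord <- order(all_pos)
    haps <- rbind(haps, matrix(0L, length(dpos), ncol(haps)))[ord, , drop = FALSE]
    outg <- c(outg, rep(1L, length(dpos)))[ord]
    pos0 <- all_pos[ord]
  }

  nuc <- c("A", "C", "G", "T")
  ref <- nuc[sample.int(4, length(pos0), replace = TRUE)]
  alt <- nuc[(match(ref, nuc) + sample.int(3, length(pos0), replace = TRUE) - 1) %% 4 + 1]

  inds <- c(sprintf("wild_%02d", seq_len(params$n_sample_wild)),
            sprintf("dom_%02d", seq_len(params$n_sample_dom)))
  pop <- c(rep("wild", params$n_sample_wild),
           rep("domestic", params$n_sample_dom))

  panel <- haplotype_panel(chrom = "1", pos = pos0 + 1, ref = ref, alt = alt,
                           haps = haps, individuals = inds, pop = pop,
                           ancestral_is_ref = rep(TRUE, length(pos0)),
                           phased = TRUE)
  # truth interval = classical hitchhiking footprint around the selected
  # site, s / (rec * ln(2 N s)), computed from parameters alone: a sweep is
  # a region-scale signal and window scans are judged against the region
  truth <- if (is.null(sw)) {
    interval_set(character(), numeric(), numeric())
  } else {
    f <- sw$s / (params$rec * log(2 * params$N_dom * sw$s))
    truth <- interval_set("1", max(0, res$sweep_pos - f / 2),
                          min(params$L, res$sweep_pos + f / 2),
                          name = "sweep", score = sw$s)
    truth$site <- res$sweep_pos
    truth
  }
  structure(list(panel = panel, truth = truth, outgroup = outg,
                 sweep = list(attempts = res$sweep_attempts,
                              final_freq = res$sweep_final_freq,
                              pos = res$sweep_pos),
                 params = params),
            class = "sim_result")
}

#' Write a simulation result bundle to disk
#'
#' Panel as VCF (with AA tags), truth sweeps as BED, population map as TSV,
#' and the parameters as a JSON sidecar.
#'
#' @param sim A `sim_result` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_result <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$panel, file.path(dir, "panel.vcf"))
  write_bed(sim$truth, file.path(dir, "truth_sweeps.bed"))
  write_pop_map(data.frame(individual = sim$panel$individuals,
                           population = as.character(sim$panel$pop)),
                file.path(dir, "pop_map.tsv"))
  p <- sim$params
  p$sweep <- if (is.null(p$sweep)) NULL else p$sweep
  jsonlite::write_json(unclass(p), file.path(dir, "params.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Simulate a CNV read-depth intensity matrix
#'
#' Per region, a duplication allele segregates at frequency
#' `0.5 - delta/2` in the wild and `0.5 + delta/2` in the domestic
#' population; each individual's copy number is Binomial(2, q) and the
#' normalized depth is `copy_number / 2 + Normal(0, sigma)` noise. With
#' `delta = 1` the two populations are fixed for different copy numbers and
#' V_ST approaches 1 as `sigma` shrinks.
#'
#' @param n_per_pop Integer vector of individuals per population (length 2,
#'   names used as population labels; default wild/domestic).
#' @param n_regions Number of CNV regions.
#' @param delta_freq Copy-frequency difference per region in `[0, 1]`;
#'   scalar or length `n_regions`.
#' @param sigma Gaussian depth-noise standard deviation (> 0).
#' @param seed Integer seed.
#' @param region_length Length of each region, bp.
#' @param chrom_length Chromosome length on which regions are spaced.
#' @return A list of class `cnv_matrix`: `regions` ([interval_set()]),
#'   `depth` (individuals x regions), `pop` (factor), `truth` (data frame of
#'   per-region `delta_freq`).
#' @export
simulate_cnv_matrix <- function(n_per_pop = c(wild = 20, domestic = 20),
                                n_regions = 100, delta_freq = 0,
                                sigma = 0.1, seed = 1, region_length = 5000,
                                chrom_length = NULL) {
  stopifnot(length(n_per_pop) == 2, all(n_per_pop >= 2), sigma > 0,
            all(delta_freq >= 0), all(delta_freq <= 1), n_regions >= 1)
  delta <- rep_len(delta_freq, n_regions)
  if (is.null(names(n_per_pop))) names(n_per_pop) <- c("wild", "domestic")
  set.seed(seed)
  n_tot <- sum(n_per_pop)
  pop <- factor(rep(names(n_per_pop), n_per_pop), levels = names(n_per_pop))
  q <- rbind(0.5 - delta / 2, 0.5 + delta / 2) # rows: pop 1, pop 2
  depth <- matrix(NA_real_, n_tot, n_regions)
  for (r in seq_len(n_regions)) {
    cn <- stats::rbinom(n_tot, 2, q[as.integer(pop), r])
    depth[, r] <- cn / 2 + stats::rnorm(n_tot, 0, sigma)
  }
  if (is.null(chrom_length)) chrom_length <- n_regions * 2 * region_length
  starts <- round(seq(0, chrom_length - region_length,
                      length.out = n_regions))
  regions <- interval_set("1", starts, starts + region_length,
                          name = sprintf("cnvr_%03d", seq_len(n_regions)))
  rownames(depth) <- sprintf("%s_%02d", pop, stats::ave(seq_len(n_tot),
                                                        pop, FUN = seq_along))
  structure(list(regions = regions, depth = depth, pop = pop,
                 truth = data.frame(region = regions$name,
                                    delta_freq = delta)),
            class = "cnv_matrix")
}

#' Simulate QTL intervals with controllable sweep enrichment
#'
#' Places `n` intervals on a chromosome; a fraction `enrichment` is centred
#' within `d` bp of a (random) truth-sweep centre, the rest uniformly.
#'
#' @param chrom_length Chromosome length, bp.
#' @param n Number of intervals (>= 1).
#' @param length_dist `c(mean, sd)` of interval lengths, bp (truncated below
#'   at 1).
#' @param enrichment Proportion in `[0, 1]` placed near truth sweeps.
#' @param truth An [interval_set()] of sweep locations (required when
#'   `enrichment > 0`).
#' @param d Maximum distance (bp) between an enriched interval's centre and
#'   a sweep centre.
#' @param seed Integer seed.
#' @return An [interval_set()].
#' @export
simulate_qtl_intervals <- function(chrom_length, n, length_dist = c(5e4, 1e4),
                                   enrichment = 0, truth = NULL, d = 0,
                                   seed = 1) {
  stopifnot(n >= 1, enrichment >= 0, enrichment <= 1)
  if (enrichment > 0 && (is.null(truth) || !nrow(truth)))
    stop("enrichment > 0 requires a non-empty truth interval set")
  set.seed(seed)
  len <- pmax(1, round(stats::rnorm(n, length_dist[1], length_dist[2])))
  len <- pmin(len, chrom_length)
  near <- seq_len(n) <= round(enrichment * n)
  centre <- numeric(n)
  unif_centre <- function(l) l / 2 + stats::runif(length(l)) * (chrom_length - l)
  centre[!near] <- unif_centre(len[!near])
  if (any(near)) {
    sc <- (truth$start + truth$end) / 2
    anchor <- sc[sample.int(length(sc), sum(near), replace = TRUE)]
    centre[near] <- anchor + stats::runif(sum(near), -d, d)
  }
  start <- pmax(0, round(centre - len / 2))
  end <- pmin(chrom_length, start + len)
  start <- pmax(0, end - len) # keep full length where clamped at the right
  interval_set("1", start, end, name = sprintf("qtl_%03d", seq_len(n)))
}
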