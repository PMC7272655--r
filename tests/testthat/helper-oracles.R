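# Independent brute-force oracles used to cross-check the implementation.

# mean pairwise difference per bp over all haplotype pairs (O(n^2 sites))
oracle_pi <- function(hapmat, length_bp) {
  n <- ncol(hapmat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- hapmat[, i]; b <- hapmat[, j]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) tot <- tot + sum(a[ok] != b[ok])
  }
  tot / choose(n, 2) / length_bp
}

# per-site pi by averaging over complete-case pairs (matches the estimator's
# site-wise complete-case convention)
oracle_window_pi <- function(hapmat, length_bp) {
  tot <- 0
  for (s in seq_len(nrow(hapmat))) {
    x <- hapmat[s, ]
    x <- x[!is.na(x)]
    if (length(x) >= 2) tot <- tot + mean(outer(x, x, "!=")[upper.tri(diag(length(x)))])
  }
  tot / length_bp
}

# Weir-Cockerham via R's one-way ANOVA machinery on allele indicators
oracle_wc_fst <- function(derived, total) {
  allele <- unlist(mapply(function(k, n) c(rep(1, k), rep(0, n - k)),
                          derived, total, SIMPLIFY = FALSE))
  pop <- factor(rep(seq_along(total), total))
  av <- suppressWarnings(stats::anova(stats::lm(allele ~ pop)))
  msb <- av["pop", "Mean Sq"]; msw <- av["Residuals", "Mean Sq"]
  N <- sum(total); r <- length(total)
  n_c <- (N - sum(total^2) / N) / (r - 1)
  a <- (msb - msw) / n_c
  list(a = a, b = msw, fst = a / (a + msw))
}

# V_ST by direct transcription with explicit population variances
oracle_vst <- function(x1, x2) {
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  v_t <- pv(c(x1, x2))
  if (v_t == 0) return(NA_real_)
  v_s <- (length(x1) * pv(x1) + length(x2) * pv(x2)) /
    (length(x1) + length(x2))
  min(max((v_t - v_s) / v_t, 0), 1)
}

# Reynolds theta by explicit double loop over loci and the two alleles
oracle_reynolds <- function(p1, p2) {
  num <- den <- 0
  for (l in seq_along(p1)) {
    for (al in 1:2) {
      a1 <- if (al == 1) p1[l] else 1 - p1[l]
      a2 <- if (al == 1) p2[l] else 1 - p2[l]
      num <- num + (a1 - a2)^2
    }
    den <- den + 2 * (1 - (p1[l] * p2[l] + (1 - p1[l]) * (1 - p2[l])))
  }
  theta <- num / den
  if (theta >= 1) Inf else -log(1 - theta)
}

# haplotype r^2 from explicit two-locus haplotype counts
oracle_r2 <- function(hap_a, hap_b) {
  p_a <- mean(hap_a); p_b <- mean(hap_b)
  p_ab <- mean(hap_a == 1 & hap_b == 1)
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# neutral log-likelihood by plain midpoint Riemann sum on p in (0,1), at a
# caller-chosen density, plus the boundary atoms — independent of the
# quantile-quadrature route
oracle_snp_loglik <- function(k, n, p_ref, omega, n_grid = 20000) {
  sd <- sqrt(omega * p_ref * (1 - p_ref))
  p <- (seq_len(n_grid) - 0.5) / n_grid
  w <- stats::dnorm(p, p_ref, sd) / n_grid
  a0 <- stats::pnorm(0, p_ref, sd)
  a1 <- stats::pnorm(1, p_ref, sd, lower.tail = FALSE)
  log(sum(w * stats::dbinom(k, n, p)) + a0 * (k == 0) + a1 * (k == n))
}

# random tree with strictly positive branch lengths -> additive matrix
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = cophenetic(tr))
}
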