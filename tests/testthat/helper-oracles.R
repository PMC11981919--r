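# Independent oracles used across test files.

# brute-force dense-grid beta-binomial rho MLE (mean fixed at pooled VAF),
# written directly from the density, independent of the package kernel
dense_rho_oracle <- function(nv, nr, grid = rho_grid()) {
  mu <- sum(nv) / sum(nr)
  ll <- vapply(grid, function(rho) {
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    keep <- nr > 0
    sum(lbeta(nv[keep] + a, nr[keep] - nv[keep] + b) - lbeta(a, b))
  }, 0)
  grid[which.max(ll)]
}

# dense grid search over the 2-signature simplex for exposure fitting
two_sig_grid_oracle <- function(counts, refs, sigs, step = 1e-3) {
  w1 <- seq(0, 1, by = step)
  ll <- vapply(w1, function(w) {
    m <- w * refs[, sigs[1]] + (1 - w) * refs[, sigs[2]]
    sum(counts * log(pmax(m, 1e-300)))
  }, 0)
  w1[which.max(ll)]
}

# plain (untruncated) binomial mixture log-likelihood
plain_mix_loglik <- function(nv, nr, p, w) {
  sum(log(vapply(seq_along(nv), function(i)
    sum(w * dbinom(nv[i], nr[i], p)), 0)))
}

# simulate region SNV counts for a gain acquired at molecular time t:
# pre-gain mutations on 2 copies (duplicated with prob 1/2), post-gain on 3
simulate_gain_counts <- function(t, n, depth, clonal_scaling = 1,
                                 size = 30) {
  dup <- runif(n) < t / (3 - t)
  p <- ifelse(dup, 2 / 3, 1 / 3) * clonal_scaling
  nr <- rnbinom(n, size = size, mu = depth)
  list(nv = rbinom(n, nr, p), nr = nr, dup = dup)
}

# small fast generator settings for structural tests
fast_sim_config <- function(...) {
  sim_config(n_donors = 2, glands_per_donor = 4, age_range = c(40, 60),
             snv_rate = 8, indel_rate = 1, n_germline_sites = 60,
             n_phased_snps = 20, artifact_rate = 20, trisomy_prob = 0,
             driver_prob = 0.2, seed = 1, ...)
}
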