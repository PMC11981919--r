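# Truncated binomial VAF mixture, sensitivity and corrected burden.

test_that("single-clone VAFs are recovered as one component", {
  set.seed(31)
  nr <- rep(40, 500)
  nv <- rbinom(500, nr, 0.4)
  k <- nv >= 4
  f <- fit_vaf_mixture(nv[k], nr[k], seed = 1)
  expect_equal(f$K, 1)
  expect_lt(abs(f$peaks - 0.4), 0.02)
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
})

test_that("two clones at distinct VAFs are both recovered", {
  set.seed(32)
  n <- 500
  comp <- runif(n) < 0.7
  nr <- rep(60, n)
  nv <- rbinom(n, nr, ifelse(comp, 0.45, 0.10))
  k <- nv >= 4
  f <- fit_vaf_mixture(nv[k], nr[k], seed = 3)
  expect_equal(f$K, 2)
  expect_lt(abs(f$peaks[1] - 0.10), 0.03)
  expect_lt(abs(f$peaks[2] - 0.45), 0.03)
})

test_that("degenerate all-variant-read samples hit the upper bound, flagged", {
  f <- fit_vaf_mixture(rep(30, 20), rep(30, 20), seed = 1)
  expect_true(f$degenerate)
  expect_gt(max(f$peaks), 0.99)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 200
    nr <- rnbinom(n, size = 30, mu = 23)
    nv <- rbinom(n, nr, runif(1, 0.2, 0.5))
    k <- nv >= 4
    if (sum(k) < 10) next
    f <- fit_vaf_mixture(nv[k], nr[k], k_max = 3, seed = rep)
    expect_true(all(diff(f$trace) >= -1e-6))
  }
})

test_that("with min_reads = 0 the truncated likelihood is plain binomial", {
  set.seed(34)
  nr <- rnbinom(100, size = 30, mu = 23)
  nv <- rbinom(100, nr, 0.35)
  p0 <- c(0.2, 0.5); w0 <- c(0.4, 0.6)
  r <- gastroclone:::tbmix_em_cpp(as.integer(nv), as.integer(nr), p0, w0,
                                  0L, 1L, 1e-6)
  expect_equal(r$trace[1], plain_mix_loglik(nv, nr, p0, w0),
               tolerance = 1e-8)
  # and the K = 1 MLE is the closed-form pooled VAF
  f <- gastroclone:::tbmix_em_cpp(as.integer(nv), as.integer(nr), 0.2, 1,
                                  0L, 200L, 1e-10)
  expect_equal(f$p, sum(nv) / sum(nr), tolerance = 1e-6)
})

test_that("refusals: too few variants, sub-threshold support", {
  expect_error(fit_vaf_mixture(rep(10, 5), rep(20, 5)), "at least 10")
  expect_error(fit_vaf_mixture(c(rep(10, 10), 2), rep(20, 11)),
               "min_reads")
})

test_that("sensitivity matches exact binomial tail sums", {
  expect_equal(estimate_sensitivity(rep(30, 7), 0.5)$S, 1 - 4526 / 2^30,
               tolerance = 1e-12)
  expect_equal(estimate_sensitivity(rep(8, 3), 0.25)$S,
               1 - pbinom(3, 8, 0.25), tolerance = 1e-12)
  expect_equal(round(estimate_sensitivity(rep(8, 3), 0.25)$S, 4), 0.1138)
  expect_equal(estimate_sensitivity(c(3, 3, 2), 0.5)$S, 0)
  expect_error(estimate_sensitivity(numeric(0), 0.5), "empty")
  expect_error(estimate_sensitivity(30, 1.2), "peak_vaf")
})

test_that("sensitivity is monotone in depth and peak VAF", {
  depths <- seq(5, 60, by = 5)
  S_depth <- vapply(depths, function(d) estimate_sensitivity(d, 0.3)$S, 0)
  expect_true(all(diff(S_depth) > 0))
  peaks <- seq(0.05, 0.9, by = 0.05)
  S_peak <- vapply(peaks, function(p) estimate_sensitivity(23, p)$S, 0)
  expect_true(all(diff(S_peak) > 0))
})

test_that("burden correction divides by sensitivity", {
  expect_equal(corrected_burden(100, 1)$corrected, 100)
  expect_equal(corrected_burden(100, 0.8)$corrected, 125)
  expect_equal(corrected_burden(95, 0.95)$corrected, 100)
  expect_gte(corrected_burden(7, 0.3)$corrected, 7)  # corrected >= raw
  b0 <- corrected_burden(10, 0)
  expect_true(b0$excluded)
  expect_true(is.na(b0$corrected))
})

test_that("median VAF drives the clonality call with a strict boundary", {
  r <- median_vaf_and_clonality(c(5, 4, 9), c(10, 10, 20))
  expect_equal(r$median_vaf, 0.45)
  expect_true(r$monoclonal)
  r2 <- median_vaf_and_clonality(c(1, 2, 3), c(10, 10, 20))
  expect_false(r2$monoclonal)
  r3 <- median_vaf_and_clonality(c(1, 5, 9), c(4, 20, 36))
  expect_equal(r3$median_vaf, 0.25)
  expect_false(r3$monoclonal)       # exactly 0.25 is polyclonal
  expect_true(is.na(median_vaf_and_clonality(integer(0), integer(0))$median_vaf))
})

test_that("estimate_burdens corrects burdens towards the true counts", {
  cfg <- sim_config(n_donors = 1, glands_per_donor = 5, seed = 41)
  co <- simulate_cohort(cfg)
  cm <- co$donors$D01$count_matrix
  cl <- classify_variants(cm)
  b <- estimate_burdens(cm, cl)
  md <- co$metadata
  expect_equal(b$sample, md$sample)
  expect_true(all(b$corrected_snv >= b$raw_snv))
  # corrected burden within 10% of the generated truth
  expect_true(all(abs(b$corrected_snv - md$true_snv) / md$true_snv < 0.10))
  expect_true(all(b$monoclonal))
  expect_true(all(b$S > 0.8 & b$S <= 1))
})
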