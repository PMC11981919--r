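# Driver-clone epithelium fraction.

test_that("cell fractions are VAF x ploidy, capped at 1", {
  expect_equal(as.numeric(cell_fraction(0.25, 2)), 0.5)
  expect_equal(as.numeric(cell_fraction(0.9, 1)), 0.9)
  cf <- cell_fraction(0.6, 2)
  expect_equal(as.numeric(cf), 1)
  expect_true(attr(cf, "capped"))
  expect_error(cell_fraction(1.2, 2))
})

test_that("driver annotation follows gene role and consequence", {
  v <- data.frame(gene = c("ARID1A", "ARID1A", "BRAF", "TTN"),
                  consequence = c("nonsense", "synonymous", "missense",
                                  "missense"))
  ann <- annotate_drivers(v, hotspots = data.frame(gene = "BRAF"))
  expect_equal(ann$driver, c(TRUE, FALSE, TRUE, FALSE))
  expect_warning(annotate_drivers(
    data.frame(gene = "ARID1A", consequence = "odd_term")), "unknown")
})

test_that("epithelium fraction is the area-weighted mutant fraction", {
  md <- data.frame(sample = paste0("S", 1:10), area = rep(1, 10))
  drv <- data.frame(sample = "S1", vaf = 0.25, local_ploidy = 2)
  r <- mutant_epithelium_fraction(md, drv)
  expect_equal(r$cohort_fraction, 0.05)
  r0 <- mutant_epithelium_fraction(md, drv[0, ])
  expect_equal(r0$cohort_fraction, 0)
  expect_error(mutant_epithelium_fraction(
    data.frame(sample = "S1", area = 0), drv), "> 0")
})

test_that("a cohort built with 8% mutant area is recovered within 1 point", {
  set.seed(91)
  n <- 200
  md <- data.frame(sample = paste0("S", 1:n), area = rlnorm(n, log(0.05), 0.5))
  # drivers placed on samples covering 8% of total area at cell fraction 1
  ord <- sample(n)
  cum <- cumsum(md$area[ord]) / sum(md$area)
  hit <- ord[cum <= 0.08]
  depth <- 500
  drv <- data.frame(sample = md$sample[hit],
                    vaf = rbinom(length(hit), depth, 0.5) / depth,
                    local_ploidy = 2)
  target <- sum(md$area[hit]) / sum(md$area)
  r <- mutant_epithelium_fraction(md, drv)
  expect_lt(abs(r$cohort_fraction - target), 0.01)
  expect_lt(abs(r$cohort_fraction - 0.08), 0.015)
})

test_that("the estimate is invariant to splitting a microdissection", {
  md <- data.frame(sample = c("A", "B"), area = c(2, 3))
  drv <- data.frame(sample = c("A", "B"), vaf = c(0.2, 0.4),
                    local_ploidy = 2)
  whole <- mutant_epithelium_fraction(md, drv)$cohort_fraction
  md2 <- data.frame(sample = c("A1", "A2", "B"), area = c(1, 1, 3))
  drv2 <- data.frame(sample = c("A1", "A2", "B"), vaf = c(0.2, 0.2, 0.4),
                     local_ploidy = 2)
  split <- mutant_epithelium_fraction(md2, drv2)$cohort_fraction
  expect_equal(whole, split)
})

test_that("the estimate is monotone in VAF and depressed by contamination", {
  md <- data.frame(sample = c("A", "B"), area = c(1, 1))
  est <- function(vafs) mutant_epithelium_fraction(
    md, data.frame(sample = c("A", "B"), vaf = vafs,
                   local_ploidy = 2))$cohort_fraction
  expect_lt(est(c(0.1, 0.2)), est(c(0.15, 0.2)))
  # contaminant driver-free reads scale VAFs down and lower the estimate
  contam <- 0.2
  expect_lt(est(c(0.3, 0.4) * (1 - contam)), est(c(0.3, 0.4)))
})

test_that("multiple drivers combine by max (default) or capped sum", {
  md <- data.frame(sample = "A", area = 1)
  drv <- data.frame(sample = c("A", "A"), vaf = c(0.2, 0.3),
                    local_ploidy = 2)
  expect_equal(mutant_epithelium_fraction(md, drv)$cohort_fraction, 0.6)
  expect_equal(mutant_epithelium_fraction(
    md, drv, combine = "capped_sum")$cohort_fraction, 1)
})

test_that("proportion models compare against the age-only fit", {
  set.seed(92)
  n <- 24
  d <- data.frame(age = runif(n, 30, 80),
                  ci_grade = sample(c("absent", "severe"), n, TRUE),
                  im_proportion = runif(n))
  # no covariate effect: comparisons non-significant in a null fit
  d$proportion <- 0.001 * d$age + rnorm(n, 0, 0.01)
  m0 <- fit_mutant_proportion_models(d)
  expect_true(all(m0$comparisons$p > 0.001))
  # strong chronic-inflammation effect detected
  hits <- 0
  for (r in 1:20) {
    d$proportion <- 0.001 * d$age + 0.15 * (d$ci_grade == "severe") +
      rnorm(n, 0, 0.01)
    m1 <- fit_mutant_proportion_models(d)
    p <- m1$comparisons$p[m1$comparisons$large == "age+ci"]
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # constant covariates are dropped with a warning
  d$ci_grade <- "absent"
  expect_warning(fit_mutant_proportion_models(d), "constant")
})
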