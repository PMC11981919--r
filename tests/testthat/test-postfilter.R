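# Quality, germline and overdispersion filters.

test_that("quality filter applies the ASMD/CLPM thresholds inclusively", {
  rec <- data.frame(asmd = c(140, 139, 200, 150), clpm = c(0, 0, 1, 0))
  qf <- quality_filter(rec)
  expect_equal(qf$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(quality_filter(data.frame(asmd = 1)), "clpm")
  expect_error(quality_filter(data.frame(asmd = NA, clpm = 0)), "missing")
})

test_that("germline test equals the exact lower-tail binomial", {
  expect_equal(germline_binomial_test(30, 60), pbinom(30, 60, 0.5))
  expect_gt(germline_binomial_test(30, 60), 0.5)    # germline-like
  expect_equal(germline_binomial_test(0, 60), 0.5^60)
  expect_lt(germline_binomial_test(10, 100), 1e-5)  # somatic
  expect_true(is.na(germline_binomial_test(0, 0)))
})

test_that("BH adjustment matches hand computation and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("rho separates clone-private variants from artifact scatter", {
  r_clone <- estimate_rho(c(15, rep(0, 9)), rep(30, 10))
  expect_gt(r_clone$rho, 0.1)
  r_art <- estimate_rho(rep(1, 10), rep(30, 10))
  expect_lt(r_art$rho, 0.1)
  # single informative sample: undefined, flagged
  r1 <- estimate_rho(c(5, 0), c(30, 0))
  expect_true(is.na(r1$rho))
  expect_true(r1$degenerate)
  # pooled VAF 0: boundary with degenerate flag
  r0 <- estimate_rho(rep(0, 5), rep(30, 5))
  expect_true(r0$degenerate)
  expect_equal(r0$rho, rho_grid()[1])
})

test_that("rho equals the dense-grid brute-force oracle", {
  set.seed(21)
  for (i in 1:150) {
    ns <- sample(3:10, 1)
    nr <- rnbinom(ns, size = 20, mu = sample(c(10, 23, 60), 1))
    p <- switch(sample(1:3, 1),
                rep(runif(1, 0.01, 0.2), ns),
                {x <- rep(0.001, ns); x[sample(ns, 1)] <- runif(1, .2, .6); x},
                rep(0.5, ns))
    nv <- rbinom(ns, nr, p)
    if (sum(nv) == 0 || sum(nv) == sum(nr) || sum(nr > 0) < 2) next
    r <- estimate_rho(nv, nr)
    expect_equal(r$rho, dense_rho_oracle(nv, nr))
  }
})

test_that("classification applies class-specific thresholds in order", {
  # counts tuned so rho falls between the SNV (0.1) and indel (0.15) cuts
  nv_mid <- c(1, 0, 0, 0, 1, 6, 6, 0, 1, 0)
  nv_art <- rep(1, 10)
  nv_som <- c(12, rep(0, 9))
  nv_grm <- rep(15, 10)
  nr <- rep(30, 10)
  mk <- function(classes) {
    v <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
                    var_class = classes, asmd = 200, clpm = 0)
    count_matrix(v, rbind(nv_mid, nv_art, nv_som, nv_grm),
                 rbind(nr, nr, nr, nr))
  }
  cl <- classify_variants(mk(c("SNV", "SNV", "SNV", "SNV")))
  expect_gt(cl$rho[1], 0.1); expect_lt(cl$rho[1], 0.15)
  expect_equal(cl$status, c("pass", "artifact", "pass", "germline"))
  # the same mid-rho counts as an indel fall below the 0.15 threshold
  cl2 <- classify_variants(mk(c("indel", "indel", "SNV", "SNV")))
  expect_equal(cl2$status[1], "artifact")
  # quality failure takes precedence over everything
  cmq <- mk(rep("SNV", 4))
  cmq$variants$asmd <- c(120, 200, 200, 200)
  expect_equal(classify_variants(cmq)$status[1], "quality_fail")
  # germline beats artifact: germline-like counts stay germline even though
  # their scatter is near-binomial
  expect_equal(classify_variants(mk(rep("SNV", 4)))$status[4], "germline")
})

test_that("classification is idempotent and deterministic", {
  co <- simulate_cohort(fast_sim_config())
  cm <- co$donors$D01$count_matrix
  a <- classify_variants(cm)
  b <- classify_variants(cm)
  expect_identical(a, b)
})

test_that("filter-annotated tables serialize with one row per variant", {
  co <- simulate_cohort(fast_sim_config())
  cm <- co$donors$D01$count_matrix
  cl <- classify_variants(cm)
  path <- tempfile(fileext = ".tsv")
  write_filtered_variants(cm, cl, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(cm$variants))
  expect_true(all(c("status", "germline_q", "rho") %in% names(back)))
})

test_that("germline recall and artifact ROC hold on synthetic cohorts", {
  cfg <- sim_config(n_donors = 2, glands_per_donor = 7, artifact_rate = 100,
                    seed = 11)
  co <- simulate_cohort(cfg)
  status <- origin <- NULL
  for (d in names(co$donors)) {
    cl <- classify_variants(co$donors[[d]]$count_matrix)
    status <- c(status, cl$status)
    origin <- c(origin, co$donors[[d]]$truth$origin)
  }
  # aggregate diploid depth is ~160 per germline site here (7 glands x 23)
  expect_gte(mean(status[origin == "germline"] == "germline"), 0.99)
  expect_gte(mean(status[origin == "artifact"] == "artifact"), 0.90)
  expect_lte(mean(status[origin == "somatic"] == "artifact"), 0.05)
})
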