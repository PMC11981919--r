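# Synthetic cohort generator: rates, determinism, rendering calibration.

test_that("zero-rate configuration yields a cohort with zero variants", {
  cfg <- sim_config(n_donors = 2, glands_per_donor = 3, snv_rate = 0,
                    indel_rate = 0, artifact_rate = 0, n_germline_sites = 0,
                    n_phased_snps = 0, driver_prob = 0, trisomy_prob = 0,
                    seed = 3)
  co <- simulate_cohort(cfg)
  for (d in co$donors) expect_equal(nrow(d$count_matrix$NV), 0)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(snv_rate = -1), "snv_rate")
  expect_error(sim_config(trisomy_timing = 1.5), "trisomy_timing")
  expect_error(sim_config(baseline_signature_mix = c(SBS1 = 0.5, SBS18 = 0.2,
                                                     `SBS5/40` = 0.2)),
               "baseline_signature_mix")
  expect_error(sim_config(contamination = 1), "contamination")
})

test_that("identical seed gives bit-identical cohorts", {
  cfg <- fast_sim_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$donors$D01$count_matrix$NV, b$donors$D01$count_matrix$NV)
  expect_identical(a$donors$D02$count_matrix$NR, b$donors$D02$count_matrix$NR)
  expect_identical(a$metadata, b$metadata)
})

test_that("per-gland mutation counts are Poisson with mean rate x age", {
  cfg <- sim_config(seed = 1)
  set.seed(11)
  profile <- list(donor = "D", age = 60, rate_factor = 1)
  n_snv <- replicate(400, simulate_gland(profile, cfg)$true_snv)
  target <- 27.8 * 60           # 1668
  se <- sqrt(target / 400)
  expect_lt(abs(mean(n_snv) - target), 4 * se)
  # variance consistent with Poisson (not wildly over/underdispersed)
  expect_gt(var(n_snv) / target, 0.7)
  expect_lt(var(n_snv) / target, 1.4)
})

test_that("true burden regressed on age recovers the configured rate", {
  cfg <- sim_config(seed = 1)
  set.seed(12)
  ages <- runif(500, 25, 80)
  counts <- vapply(ages, function(a)
    simulate_gland(list(donor = "D", age = a, rate_factor = 1),
                   cfg)$true_snv, 0)
  fit <- lm(counts ~ ages)
  se <- summary(fit)$coefficients["ages", "Std. Error"]
  expect_lt(abs(coef(fit)["ages"] - 27.8), 3 * se)
})

test_that("trisomy timing controls duplicated mutation counts", {
  cfg0 <- sim_config(trisomy_prob = 1, trisomy_timing = 0,
                     trisomy_chrom_fraction = 0.5, seed = 1)
  set.seed(13)
  g0 <- simulate_gland(list(donor = "D", age = 60), cfg0)
  expect_equal(sum(g0$mutations$duplicated), 0)

  cfg1 <- sim_config(trisomy_prob = 1, trisomy_timing = 1,
                     trisomy_chrom_fraction = 0.5, snv_rate = 10, seed = 1)
  set.seed(14)
  dup <- nondup <- 0
  for (i in 1:100) {
    g <- simulate_gland(list(donor = "D", age = 50), cfg1)
    m <- g$mutations[g$mutations$chrom == "chr20", ]
    dup <- dup + sum(m$duplicated)
    nondup <- nondup + sum(!m$duplicated)
  }
  # at t = 1 every chr20 mutation predates the gain; half sit on the
  # duplicated copy
  frac <- dup / (dup + nondup)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (dup + nondup)))
})

test_that("metaplastic acceleration scales signature-specific counts", {
  cfg <- sim_config(snv_rate = 27.8, indel_rate = 0, trisomy_prob = 0,
                    driver_prob = 0, seed = 1)
  set.seed(15)
  prof <- list(donor = "D", age = 60, rate_factor = 1)
  n18 <- function(meta) {
    g <- simulate_gland(prof, cfg, metaplasia = meta)
    sum(g$mutations$signature == "SBS18", na.rm = TRUE)
  }
  base <- mean(replicate(40, n18(FALSE)))
  meta <- mean(replicate(40, n18(TRUE)))
  expect_lt(abs(meta / base - 8), 1.0)
})

test_that("render_reads hits the expected VAF and depth median", {
  cfg <- sim_config(contamination = 0, seed = 1)
  n <- 1e5
  truth <- structure(list(
    trisomy = NULL,
    mutations = data.frame(chrom = "chr1", duplicated = FALSE,
                           cell_fraction = 1)[rep(1, n), ]),
    class = "gland_truth")
  set.seed(16)
  rd <- render_reads(truth, cfg)
  expect_true(all(rd$exp_vaf == 0.5))
  expect_true(median(rd$nr) >= 22 && median(rd$nr) <= 24)
  expect_lt(abs(mean(rd$nv / pmax(rd$nr, 1)) - 0.5), 0.005)

  # duplicated trisomic variant in a pure monoclonal sample: VAF 2/3
  truth_tri <- structure(list(
    trisomy = list(chrom = "chr20", parental_copy = "A", timing = 0.5),
    mutations = data.frame(chrom = "chr20", duplicated = TRUE,
                           cell_fraction = 1)[rep(1, 1000), ]),
    class = "gland_truth")
  rd2 <- render_reads(truth_tri, cfg)
  expect_true(all(abs(rd2$exp_vaf - 2 / 3) < 1e-12))
})

test_that("rendered VAFs converge to the expected VAF with depth", {
  cfg <- sim_config(contamination = 0.1, depth_median = 200,
                    depth_dispersion = 100, seed = 1)
  n <- 2e4
  truth <- structure(list(
    trisomy = NULL,
    mutations = data.frame(chrom = "chr1", duplicated = FALSE,
                           cell_fraction = 0.8)[rep(1, n), ]),
    class = "gland_truth")
  set.seed(17)
  rd <- render_reads(truth, cfg)
  v <- 0.5 * 0.8 * 0.9
  expect_lt(abs(mean(rd$nv / rd$nr) - v), 0.003)
})

test_that("germline sites sit at VAF 0.5 in all samples of a donor", {
  co <- simulate_cohort(fast_sim_config())
  d <- co$donors$D01
  gl <- d$truth$origin == "germline"
  vaf <- d$count_matrix$NV[gl, ] / pmax(d$count_matrix$NR[gl, ], 1)
  expect_lt(abs(mean(vaf) - 0.5), 0.02)
  # and artifacts scatter at low VAF across samples
  art <- d$truth$origin == "artifact"
  if (any(art)) {
    va <- d$count_matrix$NV[art, ] / pmax(d$count_matrix$NR[art, ], 1)
    expect_lt(mean(va), 0.25)
  }
})

test_that("cohort structure is internally consistent", {
  co <- simulate_cohort(fast_sim_config())
  expect_s3_class(co, "synthetic_cohort")
  for (d in names(co$donors)) {
    cm <- co$donors[[d]]$count_matrix
    expect_true(all(cm$NV <= cm$NR))
    expect_equal(nrow(co$donors[[d]]$truth), nrow(cm$NV))
    expect_true(all(colnames(cm$NV) %in% co$metadata$sample))
    # every called variant reaches min_reads support somewhere
    expect_true(all(apply(cm$NV, 1, max) >= 4))
  }
  # count matrix round-trips through TSV
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(co$donors$D01$count_matrix, path)
  back <- read_count_matrix(path)
  expect_equal(back$NV, co$donors$D01$count_matrix$NV)
  expect_equal(back$variants$pos, co$donors$D01$count_matrix$variants$pos)
})
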