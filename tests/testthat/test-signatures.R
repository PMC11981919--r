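# Catalogs, exposure EM, deconvolution and fold increases.

test_that("SBS channels follow the pyrimidine-centred convention", {
  expect_equal(sbs_channel("C", "A", "ACA"), "A[C>A]A")
  expect_equal(sbs_channel("G", "T", "TGT"), "A[C>A]A")  # reverse complement
  expect_equal(sbs_channel("T", "G", "TTT"), "T[T>G]T")
  expect_true(is.na(sbs_channel("C", "C", "ACA")))
  expect_true(is.na(sbs_channel("C", "A", "ANA")))
  expect_equal(length(sbs96_channels()), 96)
  expect_equal(anyDuplicated(sbs96_channels()), 0)
})

test_that("SBS catalogs count variants into the right channels", {
  v <- data.frame(ref = c("C", "G"), alt = c("A", "T"),
                  context = c("ACA", "TGT"))
  cat1 <- build_sbs_catalog(v)
  expect_equal(unname(cat1[["A[C>A]A"]]), 2)
  expect_equal(sum(cat1), 2)
  empty <- build_sbs_catalog(v[0, ])
  expect_equal(sum(empty), 0)
  expect_warning(bad <- build_sbs_catalog(
    data.frame(ref = "C", alt = "A", context = "NNN")), "skipped")
  expect_equal(sum(bad), 0)
})

test_that("ID channels follow the homopolymer convention", {
  expect_equal(id_channel("Ins", "T", 6), "1:Ins:T:5")
  expect_equal(id_channel("Del", "T", 6), "1:Del:T:5")
  expect_equal(id_channel("Del", "A", 1), "1:Del:T:0")  # A folds to T
  expect_equal(length(id83_channels()), 83)
  expect_equal(anyDuplicated(id83_channels()), 0)
  v <- data.frame(indel_type = c("Ins", "Del"), indel_base = c("T", "T"),
                  hp_len = c(6, 6))
  cat1 <- build_id_catalog(v)
  expect_equal(unname(cat1[["1:Ins:T:5"]]), 1)
  expect_equal(unname(cat1[["1:Del:T:5"]]), 1)
  expect_equal(sum(build_id_catalog(v[0, ])), 0)
})

test_that("catalog totals are conserved on generator output", {
  cfg <- fast_sim_config()
  co <- simulate_cohort(cfg)
  v <- co$donors$D01$count_matrix$variants
  tr <- co$donors$D01$truth
  snvs <- v[tr$origin == "somatic" & v$var_class == "SNV", ]
  cat96 <- build_sbs_catalog(snvs[setdiff(names(snvs), "channel")])
  expect_equal(sum(cat96), nrow(snvs))
  # context-derived channels agree with the generator's labels
  expect_equal(sbs_channel(snvs$ref, snvs$alt, snvs$context), snvs$channel)
  inds <- v[tr$origin == "somatic" & v$var_class == "indel", ]
  cat83 <- build_id_catalog(inds)        # generator channel labels
  expect_equal(sum(cat83), nrow(inds))
  # 1-bp events classify identically from their homopolymer annotations
  one_bp <- inds[grepl("^1:", inds$channel), ]
  cat1bp <- build_id_catalog(one_bp[setdiff(names(one_bp), "channel")])
  expect_equal(sum(cat1bp), nrow(one_bp))
  expect_equal(as.integer(cat1bp),
               as.integer(build_id_catalog(one_bp)))
})

test_that("exposure EM recovers pure and mixed reference spectra", {
  refs <- synthetic_signatures("SBS")
  e1 <- fit_exposures_em(100 * refs[, "SBS1"], refs)
  expect_gte(e1[["SBS1"]], 0.99)
  set.seed(61)
  mix <- 0.5 * refs[, "SBS1"] + 0.5 * refs[, "SBS18"]
  counts <- as.vector(rmultinom(1, 1e4, mix))
  names(counts) <- rownames(refs)
  e2 <- fit_exposures_em(counts, refs, subset = c("SBS1", "SBS18"))
  expect_lt(abs(e2[["SBS1"]] - 0.5), 0.05)
  expect_lt(abs(e2[["SBS18"]] - 0.5), 0.05)
  # single-signature subset gives exposure 1
  e3 <- fit_exposures_em(counts, refs, subset = "SBS1")
  expect_equal(as.numeric(e3), 1)
  expect_error(fit_exposures_em(0 * counts, refs), "empty catalog")
  expect_error(fit_exposures_em(counts, refs, subset = character(0)),
               "empty")
  expect_warning(fit_exposures_em(counts[1:96] * 0 + c(30, rep(0, 95)),
                                  refs), "unstable")
})

test_that("EM matches a dense grid search on two-signature problems", {
  refs <- synthetic_signatures("SBS")
  set.seed(62)
  for (i in 1:5) {
    sigs <- sample(colnames(refs), 2)
    w <- runif(1)
    mix <- w * refs[, sigs[1]] + (1 - w) * refs[, sigs[2]]
    counts <- as.vector(rmultinom(1, 5000, mix))
    names(counts) <- rownames(refs)
    em <- fit_exposures_em(counts, refs, subset = sigs)
    oracle <- two_sig_grid_oracle(counts, refs, sigs)
    expect_lt(abs(em[[sigs[1]]] - oracle), 0.01)
  }
})

test_that("EM exposure log-likelihood trace is non-decreasing", {
  refs <- synthetic_signatures("SBS")
  set.seed(63)
  counts <- as.vector(rmultinom(1, 2000, rowMeans(refs)))
  names(counts) <- rownames(refs)
  e <- fit_exposures_em(counts, refs)
  expect_true(all(diff(attr(e, "trace")) >= -1e-8))
})

test_that("deconvolution accepts reference combinations, rejects noise", {
  refs <- synthetic_signatures("SBS")
  d1 <- deconvolve_to_reference(refs[, "SBS18"], refs)
  expect_gt(d1$cosine, 0.999)
  expect_true(d1$accepted)
  mix <- 0.6 * refs[, "SBS1"] + 0.4 * refs[, "SBS18"]
  d2 <- deconvolve_to_reference(mix, refs, subset = c("SBS1", "SBS18"))
  expect_lt(abs(d2$weights[["SBS1"]] - 0.6), 0.05)
  expect_gt(d2$cosine, 0.99)
  set.seed(64)
  cs <- replicate(100, {
    x <- rexp(96); x <- x / sum(x)
    deconvolve_to_reference(x, refs)$cosine
  })
  expect_lt(mean(cs), 0.90)
  expect_gte(mean(cs < 0.90), 0.9)
})

test_that("cosine similarity is symmetric and scale-invariant", {
  set.seed(65)
  a <- rexp(96); b <- rexp(96)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_equal(cosine_similarity(a, b), cosine_similarity(10 * a, 0.1 * b))
  expect_equal(cosine_similarity(a, a), 1)
})

test_that("SBS5/40 exposures are reported combined", {
  e <- c(SBS1 = 0.2, SBS5 = 0.3, SBS18 = 0.1, SBS40a = 0.25, SBS40c = 0.15)
  m <- merge_sbs540(e)
  expect_equal(m[["SBS5/40"]], 0.7)
  expect_equal(sum(m), 1)
  expect_false(any(c("SBS5", "SBS40a", "SBS40c") %in% names(m)))
})

test_that("fold increases follow the three-step observed/expected rule", {
  base <- c(SBS1 = 0.3, SBS18 = 0.2, `SBS5/40` = 0.5)
  f1 <- signature_fold_increase(base, 1000, base, 1000)
  expect_equal(as.numeric(f1), c(1, 1, 1))
  f2 <- signature_fold_increase(base, 2000, base, 1000)
  expect_equal(as.numeric(f2), c(2, 2, 2))
  b0 <- c(SBS1 = 0, SBS18 = 0.5, `SBS5/40` = 0.5)
  f3 <- signature_fold_increase(c(SBS1 = 0.1, SBS18 = 0.45,
                                  `SBS5/40` = 0.45), 1000, b0, 1000)
  expect_true(is.infinite(f3[["SBS1"]]))
  expect_true(attr(f3, "infinite")[1])
  expect_error(signature_fold_increase(base, 100, base, 0), "expected")
})

test_that("ID2/ID1 ratio from catalogs and exposure counts", {
  expect_equal(id2_id1_ratio(c(ID1 = 10, ID2 = 10)), 1.0)
  expect_equal(id2_id1_ratio(c(ID1 = 10, ID2 = 25)), 2.5)
  expect_equal(id2_id1_ratio(c(ID1 = 10, ID2 = 0)), 0.0)
  expect_warning(r <- id2_id1_ratio(c(ID1 = 0, ID2 = 5)), "undefined")
  expect_true(is.na(r))
  v <- data.frame(indel_type = c("Ins", "Del", "Del"),
                  indel_base = c("T", "T", "T"), hp_len = c(5, 6, 4))
  expect_equal(id2_id1_ratio(build_id_catalog(v)), 2)
})

test_that("extracted-signature exposures convert by matrix product", {
  w <- rbind(E1 = c(SBS1 = 0.7, SBS18 = 0.3),
             E2 = c(SBS1 = 0.1, SBS18 = 0.9))
  e <- rbind(S1 = c(E1 = 1, E2 = 0), S2 = c(E1 = 0.5, E2 = 0.5))
  out <- convert_exposures(e, w)
  expect_equal(out["S1", ], c(SBS1 = 0.7, SBS18 = 0.3))
  expect_equal(unname(rowSums(out)), c(1, 1))
})

test_that("signature tables round-trip through COSMIC format", {
  refs <- synthetic_signatures("SBS")
  path <- tempfile(fileext = ".tsv")
  write_signatures(refs, path)
  back <- read_signatures(path)
  expect_equal(back, refs, tolerance = 1e-6)
  id <- synthetic_signatures("ID")
  expect_equal(colSums(id), setNames(rep(1, ncol(id)), colnames(id)))
})
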