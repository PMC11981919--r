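# End-to-end orchestration: simulate (or load) a cohort, filter variants,
# estimate clonality and corrected burdens, fit rate models, signature
# exposures and metaplasia folds, time copy-number gains, detect trisomies in
# emulated panel data, and estimate the driver-mutant epithelium fraction.

#' Pipeline configuration
#'
#' Bundles the simulation settings and every analysis threshold. The
#' configuration round-trips through YAML/JSON unchanged.
#'
#' @param sim A [sim_config()].
#' @param min_reads Minimum variant-supporting reads (calling truncation).
#' @param germline_q Somatic cut-off on the BH-adjusted germline q-value.
#' @param rho_snv,rho_indel Beta-binomial artifact thresholds.
#' @param cosine_accept Deconvolution acceptance threshold.
#' @param clonality_cutoff Median-VAF boundary for monoclonality.
#' @param delta_vaf Minimum haplotype VAF difference for a trisomy call.
#' @param panel_min_depth Minimum depth of panel SNP sites.
#' @param trisomy_q Significance cut-off for panel trisomy q-values.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), min_reads = 4,
                            germline_q = 1e-5, rho_snv = 0.1,
                            rho_indel = 0.15, cosine_accept = 0.90,
                            clonality_cutoff = 0.25, delta_vaf = 0.1,
                            panel_min_depth = 6, trisomy_q = 0.05,
                            seed = 1L) {
  stopifnot(rho_snv > 0, rho_indel > 0, germline_q > 0, germline_q <= 1,
            cosine_accept >= 0, cosine_accept <= 1,
            clonality_cutoff >= 0, clonality_cutoff < 1,
            delta_vaf >= 0, delta_vaf < 1, panel_min_depth >= 1,
            min_reads >= 0)
  cfg <- as.list(environment())
  class(cfg$sim) <- "sim_config"
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return The path / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  for (f in c("baseline_signature_mix", "signature_accel",
              "id_signature_mix", "id_signature_accel"))
    x$sim[[f]] <- as.list(x$sim[[f]])
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
       else yaml::read_yaml(path)
  sim <- x$sim
  x$sim <- NULL
  sim[c("baseline_signature_mix", "signature_accel", "id_signature_mix",
        "id_signature_accel")] <-
    lapply(sim[c("baseline_signature_mix", "signature_accel",
                 "id_signature_mix", "id_signature_accel")], unlist)
  do.call(pipeline_config, c(list(sim = do.call(sim_config, sim)), x))
}

# per-cohort burden table: classify each donor, estimate burdens, join
# gland metadata
.cohort_burdens <- function(cohort, cfg) {
  cls <- classify_cohort(cohort, germline_q = cfg$germline_q,
                         rho_snv = cfg$rho_snv, rho_indel = cfg$rho_indel)
  burdens <- do.call(rbind, lapply(names(cohort$donors), function(d)
    estimate_burdens(cohort$donors[[d]]$count_matrix, cls[[d]],
                     min_reads = cfg$min_reads, seed = cfg$seed)))
  list(classifications = cls,
       burdens = merge(cohort$metadata, burdens, by = "sample",
                       sort = TRUE))
}

# SBS catalog and merged exposures for one sample's passing detected SNVs
.sample_exposures <- function(cm, cls, sample, refs, min_reads) {
  i <- which(cls$status == "pass" & cm$variants$var_class == "SNV" &
               cm$NV[, sample] >= min_reads)
  if (length(i) < 10) return(NULL)
  cat96 <- suppressWarnings(build_sbs_catalog(cm$variants[i, , drop = FALSE]))
  expo <- suppressWarnings(fit_exposures_em(cat96, refs))
  merge_sbs540(expo)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort under `config$sim`, then runs filtering, clonality and
#' burden estimation, mutation-rate models, signature exposures and
#' metaplasia fold increases, copy-number-gain timing for trisomic glands,
#' panel trisomy detection (on panel counts emulated for the donor with the
#' most trisomic glands), and the driver-mutant epithelium fraction. Identical
#' configuration and seed give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for per-stage TSV/JSON outputs.
#' @return A `pipeline_report` list; see the elements `burdens`,
#'   `rate_models`, `metaplasia_folds`, `exposures`, `signature_folds`,
#'   `cnv_timing`, `trisomy`, `mutant_fraction`, `thresholds`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  cfg <- config
  cohort <- simulate_cohort(cfg$sim, seed = cfg$seed)
  cb <- .cohort_burdens(cohort, cfg)
  burdens <- cb$burdens
  cls <- cb$classifications

  ok <- !is.na(burdens$corrected_snv)
  nm <- ok & !burdens$metaplasia
  rate_models <- list()
  if (length(unique(burdens$donor[nm])) >= 2 && sum(nm) >= 3) {
    rate_models$snv <- fit_burden_rate_model(
      burdens$corrected_snv[nm], burdens$age[nm], burdens$donor[nm])
    rate_models$indel <- fit_burden_rate_model(
      burdens$corrected_indel[nm], burdens$age[nm], burdens$donor[nm])
  }

  # observed/expected folds for metaplastic glands
  metaplasia_folds <- NULL
  mrows <- which(ok & burdens$metaplasia)
  if (length(mrows) && length(rate_models)) {
    metaplasia_folds <- data.frame(
      sample = burdens$sample[mrows],
      fold_snv = burden_fold_change(burdens$corrected_snv[mrows],
                                    burdens$age[mrows], rate_models$snv),
      fold_indel = burden_fold_change(burdens$corrected_indel[mrows],
                                      burdens$age[mrows],
                                      rate_models$indel),
      stringsAsFactors = FALSE)
  }

  # signature exposures per sample; fold increases for metaplastic glands
  refs <- synthetic_signatures("SBS")
  expo_list <- list()
  for (d in names(cohort$donors)) {
    cm <- cohort$donors[[d]]$count_matrix
    for (s in colnames(cm$NV))
      expo_list[[s]] <- .sample_exposures(cm, cls[[d]], s, refs,
                                          cfg$min_reads)
  }
  keep <- !vapply(expo_list, is.null, TRUE)
  exposures <- if (any(keep)) do.call(rbind, expo_list[keep]) else NULL

  signature_folds <- NULL
  if (!is.null(exposures) && length(rate_models)) {
    signature_folds <- .signature_folds(exposures, burdens,
                                        rate_models$snv)
  }

  # molecular timing of trisomies in WGS glands
  cnv_timing <- .pipeline_cnv_timing(cohort, cls, burdens, cfg)

  # panel trisomy detection for the donor with the most trisomic glands
  trisomy <- .pipeline_trisomy(cohort, cfg)

  mutant_fraction <- .pipeline_mutant_fraction(cohort, cls, cfg)

  report <- structure(list(
    metadata = cohort$metadata, burdens = burdens,
    rate_models = rate_models, metaplasia_folds = metaplasia_folds,
    exposures = exposures, signature_folds = signature_folds,
    cnv_timing = cnv_timing, trisomy = trisomy,
    mutant_fraction = mutant_fraction,
    thresholds = cfg[c("min_reads", "germline_q", "rho_snv", "rho_indel",
                       "cosine_accept", "clonality_cutoff", "delta_vaf",
                       "panel_min_depth", "trisomy_q", "seed")]),
    class = "pipeline_report")
  if (!is.null(outdir)) .write_report(report, cohort, outdir)
  report
}

.signature_folds <- function(exposures, burdens, snv_model) {
  rows <- rownames(exposures)
  b <- burdens[match(rows, burdens$sample), ]
  nonmeta <- !b$metaplasia
  out <- list()
  for (d in unique(b$donor)) {
    base_rows <- which(b$donor == d & nonmeta)
    meta_rows <- which(b$donor == d & !nonmeta)
    if (!length(base_rows) || !length(meta_rows)) next
    baseline <- colMeans(exposures[base_rows, , drop = FALSE])
    baseline <- baseline / sum(baseline)
    for (i in meta_rows) {
      if (is.na(b$corrected_snv[i])) next
      expected <- snv_model$intercept + snv_model$slope * b$age[i]
      if (expected <= 0) next
      fold <- signature_fold_increase(exposures[i, ], b$corrected_snv[i],
                                      baseline, expected)
      out[[b$sample[i]]] <- data.frame(
        sample = b$sample[i], donor = d, signature = names(fold),
        fold = as.numeric(fold), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else NULL
}

.pipeline_cnv_timing <- function(cohort, cls, burdens, cfg) {
  out <- list()
  for (d in names(cohort$donors)) {
    cm <- cohort$donors[[d]]$count_matrix
    md <- cohort$metadata[cohort$metadata$donor == d, ]
    for (s in md$sample[md$trisomy]) {
      i <- which(cls[[d]]$status == "pass" &
                   cm$variants$var_class == "SNV" &
                   cm$variants$chrom == "chr20" &
                   cm$NV[, s] >= cfg$min_reads)
      if (length(i) < 5) next
      peak <- burdens$peak[burdens$sample == s]
      if (!length(peak) || is.na(peak)) next
      cfe <- min(2 * peak, 1)           # diploid peak ~ cfe / 2
      cs <- 3 * cfe / (cfe + 2)         # trisomic-VAF scaling
      est <- time_cnv_region(cm$NV[i, s], cm$NR[i, s],
                             cnv_region("chr20", kind = "trisomy"),
                             clonal_scaling = cs)
      out[[s]] <- data.frame(sample = s, donor = d, n_snvs = length(i),
                             T = est$T, ci_low = est$ci_low,
                             ci_high = est$ci_high, clamped = est$clamped,
                             true_timing = md$trisomy_timing[md$sample == s],
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else NULL
}

.pipeline_trisomy <- function(cohort, cfg) {
  md <- cohort$metadata
  tri_by_donor <- tapply(md$trisomy, md$donor, sum)
  if (!any(tri_by_donor > 0)) return(NULL)
  d <- names(which.max(tri_by_donor))
  cm <- cohort$donors[[d]]$count_matrix
  truth <- cohort$donors[[d]]$truth
  tri_sam <- md$sample[md$donor == d & md$trisomy]
  snp_rows <- which(truth$origin == "germline" & cm$variants$chrom == "chr20")
  if (length(snp_rows) < 10 || length(tri_sam) < 1) return(NULL)
  vaf <- cm$NV[snp_rows, tri_sam, drop = FALSE] /
    pmax(cm$NR[snp_rows, tri_sam, drop = FALSE], 1)
  phased <- suppressWarnings(
    phase_snps_from_wgs(vaf, cm$variants[snp_rows, c("chrom", "pos")]))

  # emulate a panel experiment for this donor: sites with trisomy enriched
  # anteriorly in the fundus over the antrum
  n_panel <- 24
  sites <- sample(c("fundus", "body", "antrum"), n_panel, replace = TRUE,
                  prob = c(0.45, 0.25, 0.30))
  p_tri <- c(fundus = 0.6, body = 0.35, antrum = 0.08)[sites]
  trisomic <- runif(n_panel) < p_tri
  panel <- simulate_panel_counts(n_panel, n_snps = nrow(phased),
                                 depth = 100, trisomic = trisomic,
                                 cell_fraction = 0.9)
  calls <- call_trisomies(panel$counts, min_depth = cfg$panel_min_depth,
                          q_cutoff = cfg$trisomy_q,
                          delta_vaf_min = cfg$delta_vaf)
  tab <- table(factor(sites, c("fundus", "body", "antrum")),
               factor(calls$call, c(TRUE, FALSE)))
  fisher <- fisher_exact_rxc(unclass(tab))
  list(donor = d, phased = phased,
       concordance = attr(phased, "concordance"),
       calls = cbind(calls, site = sites, truth = trisomic),
       site_table = tab, fisher_p = fisher$p.value)
}

.pipeline_mutant_fraction <- function(cohort, cls, cfg) {
  md <- cohort$metadata
  drv <- list()
  for (d in names(cohort$donors)) {
    cm <- cohort$donors[[d]]$count_matrix
    ann <- annotate_drivers(cm$variants)
    rows <- which(ann$driver & cls[[d]]$status == "pass")
    for (i in rows) {
      det <- which(cm$NV[i, ] >= cfg$min_reads)
      for (s in det)
        drv[[length(drv) + 1]] <- data.frame(
          sample = colnames(cm$NV)[s], gene = ann$gene[i],
          vaf = cm$NV[i, s] / cm$NR[i, s], local_ploidy = 2,
          stringsAsFactors = FALSE)
    }
  }
  drivers <- if (length(drv)) do.call(rbind, drv) else
    data.frame(sample = character(0), vaf = numeric(0),
               local_ploidy = numeric(0))
  mf <- mutant_epithelium_fraction(
    data.frame(sample = md$sample, area = md$area_mm2), drivers)

  agg <- tapply(mf$per_sample$area * mf$per_sample$mutant_fraction,
                md$donor[match(mf$per_sample$sample, md$sample)], sum) /
    tapply(mf$per_sample$area,
           md$donor[match(mf$per_sample$sample, md$sample)], sum)
  donor_df <- data.frame(donor = names(agg), proportion = as.numeric(agg),
                         stringsAsFactors = FALSE)
  donor_df$age <- md$age[match(donor_df$donor, md$donor)]
  donor_df$im_proportion <- tapply(md$metaplasia, md$donor,
                                   mean)[donor_df$donor]
  models <- tryCatch(
    suppressWarnings(fit_mutant_proportion_models(donor_df)),
    error = function(e) NULL)
  list(per_sample = mf$per_sample, cohort_fraction = mf$cohort_fraction,
       per_donor = donor_df, models = models)
}

.write_report <- function(report, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x))
    write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(report$burdens, "burdens.tsv")
  wt(report$metaplasia_folds, "metaplasia_folds.tsv")
  wt(report$signature_folds, "signature_folds.tsv")
  wt(report$cnv_timing, "cnv_timing.tsv")
  if (!is.null(report$trisomy)) wt(report$trisomy$calls, "trisomy_calls.tsv")
  wt(report$mutant_fraction$per_sample, "mutant_fraction.tsv")
  if (!is.null(report$exposures))
    wt(data.frame(sample = rownames(report$exposures), report$exposures,
                  check.names = FALSE), "exposures.tsv")
  hdr <- report$thresholds
  if (length(report$rate_models)) {
    hdr$snv_slope <- report$rate_models$snv$slope
    hdr$indel_slope <- report$rate_models$indel$slope
  }
  hdr$mutant_epithelium_fraction <- report$mutant_fraction$cohort_fraction
  if (!is.null(report$trisomy)) hdr$trisomy_fisher_p <- report$trisomy$fisher_p
  jsonlite::write_json(hdr, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", nrow(x$metadata), "glands,",
      length(unique(x$metadata$donor)), "donors\n")
  if (length(x$rate_models))
    cat(sprintf("  SNV rate %.1f /yr, indel rate %.2f /yr\n",
                x$rate_models$snv$slope, x$rate_models$indel$slope))
  if (!is.null(x$metaplasia_folds))
    cat(sprintf("  metaplasia folds: SNV %.2f, indel %.2f (means)\n",
                mean(x$metaplasia_folds$fold_snv, na.rm = TRUE),
                mean(x$metaplasia_folds$fold_indel, na.rm = TRUE)))
  cat(sprintf("  mutant epithelium fraction %.3f\n",
              x$mutant_fraction$cohort_fraction))
  invisible(x)
}

#' Parameter-recovery study on synthetic cohorts
#'
#' Simulates replicate cohorts at the configured generator settings, runs
#' filtering, sensitivity-corrected burden estimation and the mixed-effects
#' rate models on non-metaplastic glands, and summarizes what the pipeline
#' recovers: the SNV and indel mutation rates (slopes), the mean
#' observed/expected burden folds of metaplastic glands, and the median
#' per-signature fold increases from the three-step signature procedure.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param seed Master seed; replicate r uses `seed * 1000 + r`.
#' @param sim Base [sim_config()]; `n_metaplastic` metaplastic glands are
#'   included per cohort.
#' @param n_metaplastic Metaplastic glands per cohort (antrum).
#' @param config Analysis thresholds ([pipeline_config()] minus simulation).
#' @return List with `replicates` (one row per cohort: `snv_slope`,
#'   `indel_slope`, `mean_fold_snv`, `mean_fold_indel`) and
#'   `signature_folds` (per metaplastic gland per signature).
#' @export
recovery_study <- function(n_replicates = 20, seed = 1,
                           sim = sim_config(), n_metaplastic = 19,
                           config = pipeline_config()) {
  sim$n_metaplastic <- n_metaplastic
  refs <- synthetic_signatures("SBS")
  reps <- list()
  sig_folds <- list()
  for (r in seq_len(n_replicates)) {
    rseed <- (seed * 1000 + r) %% .Machine$integer.max
    cohort <- simulate_cohort(sim, seed = rseed)
    cfg <- config
    cfg$seed <- rseed
    cb <- .cohort_burdens(cohort, cfg)
    b <- cb$burdens
    ok <- !is.na(b$corrected_snv)
    nm <- ok & !b$metaplasia
    fit_s <- fit_burden_rate_model(b$corrected_snv[nm], b$age[nm],
                                   b$donor[nm])
    fit_i <- fit_burden_rate_model(b$corrected_indel[nm], b$age[nm],
                                   b$donor[nm])
    mrows <- which(ok & b$metaplasia)
    fold_s <- burden_fold_change(b$corrected_snv[mrows], b$age[mrows], fit_s)
    fold_i <- burden_fold_change(b$corrected_indel[mrows], b$age[mrows],
                                 fit_i)
    reps[[r]] <- data.frame(replicate = r, snv_slope = fit_s$slope,
                            indel_slope = fit_i$slope,
                            mean_fold_snv = mean(fold_s, na.rm = TRUE),
                            mean_fold_indel = mean(fold_i, na.rm = TRUE))
    # per-signature folds in metaplastic glands
    expo_list <- list()
    for (d in names(cohort$donors)) {
      cm <- cohort$donors[[d]]$count_matrix
      for (s in colnames(cm$NV))
        expo_list[[s]] <- .sample_exposures(cm, cb$classifications[[d]], s,
                                            refs, cfg$min_reads)
    }
    keep <- !vapply(expo_list, is.null, TRUE)
    if (any(keep)) {
      exposures <- do.call(rbind, expo_list[keep])
      sf <- .signature_folds(exposures, b, fit_s)
      if (!is.null(sf)) {
        sf$replicate <- r
        sig_folds[[r]] <- sf
      }
    }
  }
  list(replicates = do.call(rbind, reps),
       signature_folds = if (length(sig_folds))
         do.call(rbind, sig_folds) else NULL)
}
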