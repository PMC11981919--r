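# Variant-level post-calling filters: alignment-quality thresholds, germline
# removal by a one-sided exact binomial test on counts aggregated over largely
# diploid samples, and recurrent-artifact removal by the maximum-likelihood
# beta-binomial overdispersion (rho). Artifactual variants scatter reads
# near-binomially across samples (low rho); true clonal somatic variants are
# present at high VAF in a few samples and absent elsewhere (high rho).

#' Alignment-quality filter
#'
#' Keeps variants whose supporting reads have a median alignment score
#' (`asmd`) of at least 140 and a clipping median (`clpm`) of 0.
#'
#' @param records data.frame with numeric `asmd` and `clpm` columns.
#' @param asmd_min,clpm_max Thresholds (defaults 140 and 0).
#' @return List with `kept` and `removed` row indices and the logical `pass`
#'   vector.
#' @export
quality_filter <- function(records, asmd_min = 140, clpm_max = 0) {
  if (!all(c("asmd", "clpm") %in% names(records)))
    stop("quality_filter: records must have 'asmd' and 'clpm' columns")
  if (anyNA(records$asmd) || anyNA(records$clpm))
    stop("quality_filter: asmd/clpm must not contain missing values")
  pass <- records$asmd >= asmd_min & records$clpm <= clpm_max
  list(kept = which(pass), removed = which(!pass), pass = pass)
}

#' One-sided exact binomial germline test
#'
#' Tests aggregated counts against the heterozygous-germline expectation of
#' VAF 0.5. Somatic variants are absent from most samples, so the aggregate
#' VAF falls below 0.5; the lower tail `P(X <= nv | nr, 0.5)` is returned.
#' Small p-values are evidence *against* germline origin.
#'
#' @param nv_total,nr_total Variant-supporting reads and depth summed over
#'   largely diploid samples (vectorized).
#' @return p-values; `NA` where `nr_total` is 0 (unassessable).
#' @export
germline_binomial_test <- function(nv_total, nr_total) {
  p <- pbinom(nv_total, nr_total, 0.5)
  p[nr_total == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted values, monotone in the order statistics and `>= p`.
#' @export
bh_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' The overdispersion search grid
#'
#' `log10(rho)` from -6 to -0.05 in steps of 0.05 (120 values).
#' @return Numeric vector of rho values.
#' @export
rho_grid <- function() 10^seq(-6, -0.05, by = 0.05)

#' Maximum-likelihood beta-binomial overdispersion per variant
#'
#' For each variant, fits a beta-binomial to its per-sample counts with the
#' mean fixed at the pooled VAF `sum(nv)/sum(nr)` and returns the grid value
#' of rho maximizing the likelihood.
#'
#' @param nv,nr Matrices (variants x samples) or vectors for a single variant.
#' @param grid Rho grid (default [rho_grid()]).
#' @return data.frame with `rho`, `degenerate` (pooled VAF at 0/1 reported at
#'   the grid boundary, or fewer than two usable samples, where `rho` is `NA`)
#'   and `n_informative`.
#' @export
estimate_rho <- function(nv, nr, grid = rho_grid()) {
  if (is.null(dim(nv))) { nv <- matrix(nv, 1); nr <- matrix(nr, 1) }
  storage.mode(nv) <- "integer"
  storage.mode(nr) <- "integer"
  if (any(nv > nr)) stop("estimate_rho: nv > nr")
  res <- bb_rho_grid_cpp(nv, nr, grid)
  data.frame(rho = res$rho, degenerate = res$degenerate,
             n_informative = res$n_informative)
}

#' Classify variants: quality_fail > germline > artifact > pass
#'
#' Applies the three filters in order. The germline test aggregates counts
#' over samples flagged largely diploid at the locus; a variant is somatic
#' when its BH-adjusted lower-tail binomial p-value is below `germline_q`
#' (default 1e-5), otherwise germline. Among somatic variants, those with
#' overdispersion below the class-specific threshold (0.1 for SNVs, 0.15 for
#' indels) are artifacts. Variants with no diploid coverage are unassessable
#' for germline status and kept, with a warning; variants with undefined rho
#' (a single informative sample) pass the artifact filter, flagged.
#'
#' @param cm A [count_matrix].
#' @param germline_q Somatic cut-off on the adjusted germline q-value.
#' @param rho_snv,rho_indel Artifact thresholds on rho.
#' @param asmd_min,clpm_max Quality thresholds.
#' @return data.frame (one row per variant): `status` in
#'   `quality_fail`/`germline`/`artifact`/`pass`, `germline_p`, `germline_q`,
#'   `rho`, `rho_degenerate`, `unassessable`.
#' @export
classify_variants <- function(cm, germline_q = 1e-5, rho_snv = 0.1,
                              rho_indel = 0.15, asmd_min = 140,
                              clpm_max = 0) {
  v <- cm$variants
  n <- nrow(v)
  q_pass <- if (all(c("asmd", "clpm") %in% names(v)))
    quality_filter(v, asmd_min, clpm_max)$pass else rep(TRUE, n)

  NVd <- cm$NV; NVd[!cm$diploid] <- 0L
  NRd <- cm$NR; NRd[!cm$diploid] <- 0L
  nv_tot <- rowSums(NVd)
  nr_tot <- rowSums(NRd)
  gp <- germline_binomial_test(nv_tot, nr_tot)
  gq <- bh_adjust(gp)
  unassess <- is.na(gp)
  if (any(unassess & q_pass))
    warning(sum(unassess & q_pass),
            " variant(s) had no diploid coverage; germline status",
            " unassessable, kept")
  somatic <- !unassess & gq < germline_q

  rho <- estimate_rho(cm$NV, cm$NR)
  thr <- ifelse(v$var_class == "indel", rho_indel, rho_snv)
  artifact <- !is.na(rho$rho) & !rho$degenerate & rho$rho < thr

  status <- rep("pass", n)
  status[somatic & artifact] <- "artifact"
  status[!somatic & !unassess] <- "germline"
  status[!q_pass] <- "quality_fail"

  data.frame(status = status, germline_p = gp, germline_q = gq,
             rho = rho$rho, rho_degenerate = rho$degenerate,
             n_informative = rho$n_informative,
             unassessable = unassess, stringsAsFactors = FALSE)
}

#' Write a filter-annotated variant table
#'
#' One row per variant: the annotation columns of the count matrix plus the
#' classification fields (status, germline p/q, rho).
#'
#' @param cm A [count_matrix].
#' @param classification Output of [classify_variants()] for `cm`.
#' @param path Output TSV path.
#' @export
write_filtered_variants <- function(cm, classification, path) {
  stopifnot(nrow(cm$variants) == nrow(classification))
  write.table(cbind(cm$variants, classification), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter every donor of a cohort
#'
#' Runs [classify_variants()] per donor (the BH family is all variants of one
#' donor) and returns the classifications alongside the cohort.
#'
#' @param cohort A `synthetic_cohort` (or any list with `donors`, each having
#'   a `count_matrix`).
#' @param ... Passed to [classify_variants()].
#' @return Named list of classification data.frames, one per donor.
#' @export
classify_cohort <- function(cohort, ...) {
  lapply(cohort$donors, function(d) classify_variants(d$count_matrix, ...))
}
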