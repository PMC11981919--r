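# Molecular timing of copy-number gains. SNVs in a gained region cluster at
# two VAFs (e.g. 2/3 for mutations duplicated by the gain, 1/3 for later
# single-copy mutations in a trisomy); the proportions of duplicated (P_D)
# and non-duplicated (P_ND) mutations time the gain as
#   T = CN_total / (CN_dup + P_ND / P_D),
# with T in [0, 1] spanning the lineage's mutation time.

#' Define a copy-number-gained region
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive coordinates.
#' @param kind `"trisomy"` (CN 3, duplicated 2) or `"cnnloh"` (copy-neutral
#'   LOH: CN 2, duplicated 2), or `"custom"` with explicit copy numbers.
#' @param cn_total,cn_dup Total and duplicated copy number (for `"custom"`).
#' @return Object of class `cnv_region`.
#' @export
cnv_region <- function(chrom, start = 1, end = .Machine$integer.max,
                       kind = c("trisomy", "cnnloh", "custom"),
                       cn_total = NULL, cn_dup = NULL) {
  kind <- match.arg(kind)
  cn <- switch(kind, trisomy = c(3, 2), cnnloh = c(2, 2),
               custom = c(cn_total, cn_dup))
  if (length(cn) != 2 || cn[1] < cn[2] || cn[2] < 1)
    stop("cnv_region: need cn_total >= cn_dup >= 1")
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 cn_total = cn[1], cn_dup = cn[2]), class = "cnv_region")
}

#' Read copy-number region definitions from a BED-style TSV
#'
#' Expects columns `chrom`, `start`, `end` and either `kind`
#' (trisomy/cnnloh) or explicit `cn_total`/`cn_dup`.
#'
#' @param path TSV path.
#' @return List of [cnv_region] objects.
#' @export
read_cnv_regions <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(d)))
  lapply(seq_len(nrow(d)), function(i) {
    if (!is.null(d$kind) && d$kind[i] %in% c("trisomy", "cnnloh"))
      cnv_region(d$chrom[i], d$start[i], d$end[i], d$kind[i])
    else cnv_region(d$chrom[i], d$start[i], d$end[i], "custom",
                    cn_total = d$cn_total[i], cn_dup = d$cn_dup[i])
  })
}

#' Assign region SNVs to duplicated/non-duplicated clusters
#'
#' Two-component binomial mixture with means fixed at the copy-number-expected
#' VAFs (`clonal_scaling * cn_dup / cn_total` and `clonal_scaling /
#' cn_total`); only the mixing weights are estimated (EM). Each SNV goes to
#' the component with the higher posterior responsibility; ties go to the
#' non-duplicated cluster so that timing is not inflated.
#'
#' @param nv,nr Counts of the SNVs inside the region (>= 5 SNVs).
#' @param region A [cnv_region].
#' @param clonal_scaling Fraction of cells in the clone carrying the gain
#'   (scales both cluster means; 1 for a pure monoclonal sample).
#' @return Object of class `dup_cluster`: `n_dup`, `n_nondup`, `p_dup`,
#'   `p_nondup`, `expected_vafs`, `assignment`.
#' @export
cluster_cn_mutations <- function(nv, nr, region, clonal_scaling = 1) {
  if (length(nv) < 5)
    stop("cluster_cn_mutations: need at least 5 SNVs in the region, got ",
         length(nv))
  m_dup <- clonal_scaling * region$cn_dup / region$cn_total
  m_nd <- clonal_scaling / region$cn_total
  w <- c(0.5, 0.5)
  ll_prev <- -Inf
  for (it in 1:500) {
    l1 <- log(w[1]) + dbinom(nv, nr, m_dup, log = TRUE)
    l2 <- log(w[2]) + dbinom(nv, nr, m_nd, log = TRUE)
    mx <- pmax(l1, l2)
    den <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    ll <- sum(den)
    r1 <- exp(l1 - den)
    if (abs(ll - ll_prev) < 1e-10) break
    ll_prev <- ll
    w <- c(mean(r1), 1 - mean(r1))
    w <- pmax(w, 1e-12); w <- w / sum(w)
  }
  dup <- r1 > 0.5                      # ties (r1 == 0.5) -> non-duplicated
  structure(list(n_dup = sum(dup), n_nondup = sum(!dup),
                 p_dup = mean(dup), p_nondup = mean(!dup),
                 expected_vafs = c(dup = m_dup, nondup = m_nd),
                 weights = w, assignment = dup, loglik = ll),
            class = "dup_cluster")
}

.timing_from_ratio <- function(ratio_nd_d, region) {
  t <- region$cn_total / (region$cn_dup + ratio_nd_d)
  pmin(t, 1)
}

#' Point estimate of copy-number-gain timing
#'
#' `T = CN_total / (CN_dup + P_ND / P_D)`, clamped to 1 when sampling noise
#' pushes the raw value above 1.
#'
#' @param cluster A `dup_cluster`.
#' @param region A [cnv_region].
#' @return Object of class `timing_estimate` (without interval; see
#'   [timing_confidence()]): `T`, `clamped`, `degenerate`.
#' @export
time_cnv <- function(cluster, region) {
  if (cluster$p_dup == 0) {
    return(structure(list(T = 0, clamped = FALSE, degenerate = TRUE,
                          region = region), class = "timing_estimate"))
  }
  raw <- region$cn_total /
    (region$cn_dup + cluster$p_nondup / cluster$p_dup)
  structure(list(T = min(raw, 1), clamped = raw > 1, degenerate = FALSE,
                 region = region), class = "timing_estimate")
}

#' Exact confidence interval for the timing
#'
#' Treats the rounded duplicated and non-duplicated counts as Poisson; the
#' exact (Clopper-Pearson / conditional binomial) 95 % interval for the
#' non-duplicated fraction is transformed through the timing formula and
#' clamped to \[0, 1\]. Equivalent to the exact Poisson ratio test interval.
#'
#' @param n_dup,n_nondup Rounded cluster counts (not both 0).
#' @param region A [cnv_region].
#' @param conf Confidence level (0.95).
#' @return `c(ci_low, ci_high)`.
#' @export
timing_confidence <- function(n_dup, n_nondup, region, conf = 0.95) {
  n_dup <- round(n_dup); n_nondup <- round(n_nondup)
  n <- n_dup + n_nondup
  if (n == 0) stop("timing_confidence: both counts are 0")
  a <- (1 - conf) / 2
  x <- n_nondup
  q_lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  q_hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  r_lo <- q_lo / (1 - q_lo)
  r_hi <- if (q_hi >= 1) Inf else q_hi / (1 - q_hi)
  lo <- if (is.infinite(r_hi)) 0 else .timing_from_ratio(r_hi, region)
  hi <- .timing_from_ratio(r_lo, region)
  c(ci_low = max(0, lo), ci_high = min(1, hi))
}

#' Time a copy-number gain from region SNV counts
#'
#' Convenience wrapper: cluster, point estimate, confidence interval.
#'
#' @inheritParams cluster_cn_mutations
#' @param conf Confidence level.
#' @return `timing_estimate` with `T`, `ci_low`, `ci_high`, `clamped`,
#'   `cluster`.
#' @export
time_cnv_region <- function(nv, nr, region, clonal_scaling = 1,
                            conf = 0.95) {
  cl <- cluster_cn_mutations(nv, nr, region, clonal_scaling)
  est <- time_cnv(cl, region)
  ci <- if (cl$n_dup + cl$n_nondup > 0)
    timing_confidence(cl$n_dup, cl$n_nondup, region, conf)
  else c(ci_low = NA_real_, ci_high = NA_real_)
  est$ci_low <- unname(ci[1]); est$ci_high <- unname(ci[2])
  est$cluster <- cl
  est
}

#' @export
print.timing_estimate <- function(x, ...) {
  cat(sprintf("CNV timing T = %.3f", x$T))
  if (!is.null(x$ci_low)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$ci_low,
                                      x$ci_high))
  if (isTRUE(x$clamped)) cat(" [clamped]")
  if (isTRUE(x$degenerate)) cat(" [degenerate: no duplicated mutations]")
  cat("\n")
  invisible(x)
}

#' Convert molecular timing to an approximate age
#'
#' Interprets T as the fraction of the sample's mutation time elapsed before
#' the gain: `age_estimate = T * corrected_burden / per_year_rate`.
#'
#' @param T Timing in \[0, 1\].
#' @param corrected_burden Sample's corrected SNV burden.
#' @param rate_per_year Fitted mutations/year.
#' @return Estimated age (years).
#' @export
cnv_age_estimate <- function(T, corrected_burden, rate_per_year) {
  T * corrected_burden / rate_per_year
}
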