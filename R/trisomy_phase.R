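# Trisomy detection in targeted panel samples from WGS-phased SNPs.
#
# Heterozygous SNPs on the trisomic chromosome have VAF 2/3 or 1/3 in
# whole-genome samples carrying the trisomy, which assigns them to parental
# haplotypes. In panel samples, a likelihood-ratio test compares one shared
# binomial (diploidy) against per-haplotype binomials (aneuploidy).

#' Phase SNPs from trisomic WGS samples
#'
#' In each trisomic WGS sample, SNPs with VAF > 0.5 lie on the duplicated
#' haplotype. Different samples may duplicate different parental copies, so
#' per-sample labels are harmonized against the first sample (orientation
#' flip when agreement < 50 %) and combined by majority vote.
#'
#' @param vaf Matrix of SNP VAFs (rows = SNPs, columns = trisomic WGS
#'   samples), or a vector for a single sample.
#' @param snp_info Optional data.frame (chrom, pos) aligned to rows.
#' @return Object of class `phased_snp_set`: data.frame with `haplotype`
#'   (`"A"` = duplicated in the orientation of the first sample), plus
#'   attributes `concordance` (fraction of per-sample labels agreeing with
#'   the consensus) and `source` (sample names).
#' @export
phase_snps_from_wgs <- function(vaf, snp_info = NULL) {
  if (is.null(dim(vaf))) vaf <- matrix(vaf, ncol = 1)
  if (ncol(vaf) < 1) stop("phase_snps_from_wgs: no trisomic WGS sample")
  lab <- vaf > 0.5                         # TRUE = duplicated haplotype
  for (s in seq_len(ncol(lab))[-1]) {
    if (mean(lab[, s] == lab[, 1], na.rm = TRUE) < 0.5)
      lab[, s] <- !lab[, s]                # opposite parental copy duplicated
  }
  votes <- rowMeans(lab, na.rm = TRUE)
  consensus <- votes >= 0.5
  concordance <- mean(lab == consensus, na.rm = TRUE)
  if (mean(abs(vaf - 0.5), na.rm = TRUE) < 0.05)
    warning("phase_snps_from_wgs: VAFs cluster near 0.5; weak trisomy",
            " signal, phasing unreliable (concordance ",
            round(concordance, 3), ")")
  out <- data.frame(haplotype = ifelse(consensus, "A", "B"),
                    stringsAsFactors = FALSE)
  if (!is.null(snp_info)) out <- cbind(snp_info, out)
  structure(out, concordance = concordance,
            source = colnames(vaf), class = c("phased_snp_set",
                                              "data.frame"))
}

#' Likelihood-ratio trisomy test for one panel sample
#'
#' Sites with depth `nr > min_depth - 1` are kept. Under the null the two
#' haplotype groups share one binomial success probability (the pooled VAF
#' over both groups); under the alternative each group has its own pooled
#' MLE. The statistic `2 * (ll_two - ll_one)` is referred to chi-square with
#' 1 degree of freedom.
#'
#' @param nv_a,nr_a Counts at haplotype-A SNP sites.
#' @param nv_b,nr_b Counts at haplotype-B SNP sites.
#' @param min_depth Minimum site depth (6, i.e. more than five reads).
#' @param null_vaf `"pooled"`: the null probability is the pooled-count MLE
#'   `sum(nv)/sum(nr)` over both groups; `"mean_site"`: the mean of per-site
#'   VAFs (documented alternative).
#' @return One-row data.frame: `ll_one`, `ll_two`, `stat`, `p`, `delta_vaf`
#'   (absolute difference of the haplotype mean site VAFs), `n_sites`,
#'   `assessable`.
#' @export
lrt_trisomy_panel <- function(nv_a, nr_a, nv_b, nr_b, min_depth = 6,
                              null_vaf = c("pooled", "mean_site")) {
  null_vaf <- match.arg(null_vaf)
  ka <- nr_a >= min_depth
  kb <- nr_b >= min_depth
  if (!any(ka) || !any(kb)) {
    return(data.frame(ll_one = NA_real_, ll_two = NA_real_, stat = NA_real_,
                      p = NA_real_, delta_vaf = NA_real_,
                      n_sites = sum(ka) + sum(kb), assessable = FALSE))
  }
  nva <- nv_a[ka]; nra <- nr_a[ka]; nvb <- nv_b[kb]; nrb <- nr_b[kb]
  ll_binom <- function(nv, nr, p) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    sum(dbinom(nv, nr, p, log = TRUE))
  }
  p0 <- if (null_vaf == "pooled") sum(nva, nvb) / sum(nra, nrb)
        else mean(c(nva / nra, nvb / nrb))
  pa <- sum(nva) / sum(nra)
  pb <- sum(nvb) / sum(nrb)
  ll_one <- ll_binom(nva, nra, p0) + ll_binom(nvb, nrb, p0)
  ll_two <- ll_binom(nva, nra, pa) + ll_binom(nvb, nrb, pb)
  stat <- max(0, 2 * (ll_two - ll_one))
  data.frame(ll_one = ll_one, ll_two = ll_two, stat = stat,
             p = pchisq(stat, 1, lower.tail = FALSE),
             delta_vaf = abs(mean(nva / nra) - mean(nvb / nrb)),
             n_sites = sum(ka) + sum(kb), assessable = TRUE)
}

#' Call trisomies across the panel samples of a donor
#'
#' Runs [lrt_trisomy_panel()] per sample, adjusts p-values by
#' Benjamini-Hochberg across all panel samples of the donor, and calls
#' trisomy when the adjusted value is significant *and* the haplotype mean
#' VAFs differ by at least `delta_vaf_min`.
#'
#' @param counts Long data.frame with columns `sample`, `haplotype`
#'   (`"A"`/`"B"`), `nv`, `nr` (e.g. from [simulate_panel_counts()]).
#' @param min_depth,null_vaf Passed to [lrt_trisomy_panel()].
#' @param q_cutoff Significance threshold on the adjusted value (0.05).
#' @param delta_vaf_min Minimum haplotype VAF difference (0.1).
#' @return data.frame, one row per sample, with `q` and logical `call`.
#' @export
call_trisomies <- function(counts, min_depth = 6, q_cutoff = 0.05,
                           delta_vaf_min = 0.1,
                           null_vaf = c("pooled", "mean_site")) {
  null_vaf <- match.arg(null_vaf)
  stopifnot(all(c("sample", "haplotype", "nv", "nr") %in% names(counts)))
  res <- lapply(split(counts, counts$sample), function(d) {
    a <- d$haplotype == "A"
    lrt_trisomy_panel(d$nv[a], d$nr[a], d$nv[!a], d$nr[!a],
                      min_depth = min_depth, null_vaf = null_vaf)
  })
  out <- do.call(rbind, res)
  out <- cbind(sample = names(res), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$call <- !is.na(out$q) & out$q < q_cutoff &
    out$delta_vaf >= delta_vaf_min
  out
}

#' Exact Fisher test for an r x c contingency table
#'
#' Full enumeration of all tables with the observed margins; the p-value is
#' the total multivariate-hypergeometric probability of tables no more
#' probable than the observed one. All-zero rows and columns are dropped
#' before enumeration; tables with a single remaining row or column give
#' p = 1.
#'
#' @param table Non-negative integer matrix.
#' @param max_tables Safety cap on the enumeration size.
#' @return List with `p.value` and `n_tables` enumerated.
#' @export
fisher_exact_rxc <- function(table, max_tables = 5e6) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("fisher_exact_rxc: table must hold non-negative integers")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    return(list(p.value = 1, n_tables = 1L))
  rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- const - sum(lgamma(m + 1))

  nr <- nrow(m); nc <- ncol(m)
  p_total <- 0
  n_tab <- 0L
  cell <- matrix(0L, nr, nc)
  # enumerate row by row, cell by cell, respecting remaining margins
  recurse <- function(i, j, row_left, col_left, lgam_acc) {
    if (n_tab > max_tables)
      stop("fisher_exact_rxc: enumeration exceeds max_tables")
    if (i == nr) {            # last row forced by column margins
      if (any(col_left < 0)) return()
      lg <- lgam_acc + sum(lgamma(col_left + 1))
      n_tab <<- n_tab + 1L
      logp <- const - lg
      if (logp <= logp_obs + 1e-7) p_total <<- p_total + exp(logp)
      return()
    }
    if (j == nc) {            # last cell of row forced by row margin
      x <- row_left
      if (x < 0 || x > col_left[nc]) return()
      cl <- col_left; cl[nc] <- cl[nc] - x
      recurse(i + 1, 1, rs[i + 1], cl, lgam_acc + lgamma(x + 1))
      return()
    }
    for (x in 0:min(row_left, col_left[j])) {
      cl <- col_left; cl[j] <- cl[j] - x
      recurse(i, j + 1, row_left - x, cl, lgam_acc + lgamma(x + 1))
    }
  }
  recurse(1, 1, rs[1], cs, 0)
  list(p.value = min(p_total, 1), n_tables = n_tab)
}
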