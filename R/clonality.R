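# Per-sample clonality and sensitivity-corrected mutation burden.
#
# Each whole-genome sample is modelled as a mixture of clones: the VAFs of its
# passing variants follow a binomial mixture truncated at the minimum number
# of supporting reads (n = 4) that variant calling imposes. The fitted peak
# feeds the detection-sensitivity estimate, and the observed burden is
# corrected by dividing over that sensitivity.

#' Fit a truncated binomial mixture to per-sample VAFs
#'
#' EM maximization of
#' `sum_i log sum_k pi_k Binom(nv_i; nr_i, p_k) / P(X >= min_reads; nr_i, p_k)`.
#' The number of components is chosen over `1..k_max` by BIC, with random
#' restarts under a fixed seed (short exploratory runs, the best of which is
#' run to convergence).
#'
#' @param nv,nr Variant-supporting reads and depths of the sample's passing
#'   variants (all `nv >= min_reads`).
#' @param k_max Largest number of components considered.
#' @param min_reads Truncation threshold (4; callers do not emit variants
#'   with fewer supporting reads).
#' @param seed Seed for the restarts.
#' @param n_restarts Random restarts per K > 1.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood tolerance.
#' @return Object of class `vaf_mixture_fit`: `K`, `peaks`, `weights`,
#'   `loglik`, `bic`, `trace` (log-likelihood per iteration of the final run),
#'   `converged`, `degenerate`, `min_reads`.
#' @export
fit_vaf_mixture <- function(nv, nr, k_max = 3, min_reads = 4, seed = 1,
                            n_restarts = 10, max_iter = 300, tol = 1e-6) {
  if (length(nv) < 10)
    stop("fit_vaf_mixture: need at least 10 passing variants, got ",
         length(nv))
  if (any(nv < min_reads))
    stop("fit_vaf_mixture: all nv must be >= min_reads")
  nv <- as.integer(nv); nr <- as.integer(nr)
  if (!is.null(seed)) set.seed(seed)

  pooled <- sum(nv) / sum(nr)
  degenerate <- pooled >= 1 - 1e-12
  if (degenerate) pooled <- 1 - 1e-6

  run <- function(p0, w0, iters)
    tbmix_em_cpp(nv, nr, p0, w0, min_reads, iters, tol)

  fits <- list()
  for (K in seq_len(k_max)) {
    if (K == 1) {
      best <- run(pooled, 1, max_iter)
    } else {
      starts <- lapply(seq_len(n_restarts), function(r) {
        p0 <- sort(runif(K, 0.03, 0.7))
        w0 <- runif(K, 0.2, 1); w0 <- w0 / sum(w0)
        run(p0, w0, 6)
      })
      ll <- vapply(starts, function(s) s$loglik, 0)
      b <- starts[[which.max(ll)]]
      best <- run(b$p, b$w, max_iter)
    }
    fits[[K]] <- best
  }
  bic <- vapply(seq_len(k_max), function(K)
    -2 * fits[[K]]$loglik + (2 * K - 1) * log(length(nv)), 0)
  K <- which.min(bic)
  f <- fits[[K]]
  ord <- order(f$p)
  structure(list(K = K, peaks = f$p[ord], weights = f$w[ord],
                 loglik = f$loglik, bic = bic[K], bic_all = bic,
                 trace = f$trace, converged = f$converged,
                 degenerate = degenerate || any(f$p > 1 - 1e-4),
                 min_reads = min_reads, n = length(nv)),
            class = "vaf_mixture_fit")
}

#' @export
print.vaf_mixture_fit <- function(x, ...) {
  cat("Truncated binomial VAF mixture:", x$K, "component(s),",
      x$n, "variants\n")
  cat(sprintf("  peak %.3f (weight %.2f)\n", x$peaks, x$weights), sep = "")
  cat("  loglik", format(x$loglik), " BIC", format(x$bic),
      if (x$degenerate) " [degenerate]" else "", "\n")
  invisible(x)
}

#' Detection sensitivity given depth distribution and VAF peak
#'
#' The probability of observing a variant in at least `min_reads` reads given
#' the per-sample coverage distribution and the observed VAF peak:
#' `S = mean_i P(X >= min_reads | nr_i, peak_vaf)` under the binomial.
#'
#' @param depths Depths at the sample's variant sites (non-empty).
#' @param peak_vaf VAF peak in (0, 1).
#' @param min_reads Minimum supporting reads (4).
#' @return Object of class `sensitivity_estimate`: `S`, `peak_used`,
#'   `depth_summary`.
#' @export
estimate_sensitivity <- function(depths, peak_vaf, min_reads = 4) {
  if (!length(depths)) stop("estimate_sensitivity: empty depth vector")
  if (peak_vaf <= 0 || peak_vaf >= 1)
    stop("estimate_sensitivity: peak_vaf must be in (0, 1)")
  S <- mean(1 - pbinom(min_reads - 1, depths, peak_vaf))
  structure(list(S = S, peak_used = peak_vaf,
                 depth_summary = summary(depths), min_reads = min_reads),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("Detection sensitivity S = %.4f (peak VAF %.3f, >= %d reads)\n",
              x$S, x$peak_used, x$min_reads))
  invisible(x)
}

#' Sensitivity-corrected mutation burden
#'
#' @param raw Observed (passing) mutation count.
#' @param S Detection sensitivity in (0, 1]; a [estimate_sensitivity()] result
#'   is also accepted. `S = 0` leaves the burden undefined (sample excluded).
#' @param var_class `"SNV"` or `"indel"` (annotation only).
#' @return Object of class `burden_estimate` with `raw`, `S`, `corrected`.
#' @export
corrected_burden <- function(raw, S, var_class = "SNV") {
  if (inherits(S, "sensitivity_estimate")) S <- S$S
  if (is.na(S) || S <= 0) {
    return(structure(list(raw = raw, S = S, corrected = NA_real_,
                          var_class = var_class, excluded = TRUE),
                     class = "burden_estimate"))
  }
  if (S > 1) stop("corrected_burden: S must be in (0, 1]")
  structure(list(raw = raw, S = S, corrected = raw / S,
                 var_class = var_class, excluded = FALSE),
            class = "burden_estimate")
}

#' @export
print.burden_estimate <- function(x, ...) {
  if (x$excluded) cat("burden undefined (S = 0); sample excluded\n")
  else cat(sprintf("%s burden: raw %d, S %.3f, corrected %.1f\n",
                   x$var_class, as.integer(x$raw), x$S, x$corrected))
  invisible(x)
}

#' Median VAF and clonality call
#'
#' The median VAF of the sample's passing variants; the gland is monoclonal
#' when it strictly exceeds 0.25 (a dominant clone at half the cells or more,
#' given diploidy).
#'
#' @param nv,nr Passing variant counts and depths (at least one variant).
#' @param cutoff Clonality boundary (0.25; the boundary itself is polyclonal).
#' @return List with `median_vaf` and `monoclonal`.
#' @export
median_vaf_and_clonality <- function(nv, nr, cutoff = 0.25) {
  if (!length(nv)) return(list(median_vaf = NA_real_, monoclonal = NA))
  m <- median(nv / nr)
  list(median_vaf = m, monoclonal = m > cutoff)
}

#' Per-sample clonality, sensitivity and corrected burdens for a donor
#'
#' For each sample: select its passing variants (status `pass`, `nv >=
#' min_reads`), fit the VAF mixture on the SNVs, take the dominant
#' (largest-weight) peak, estimate sensitivity from the depths at passing
#' sites, and correct SNV and indel burdens.
#'
#' @param cm A [count_matrix] for one donor.
#' @param classification Output of [classify_variants()] for `cm`.
#' @param min_reads Truncation/support threshold.
#' @param k_max,seed Passed to [fit_vaf_mixture()].
#' @return data.frame, one row per sample: raw and corrected burdens, `S`,
#'   `peak`, `K`, `median_vaf`, `monoclonal`, `excluded`.
#' @export
estimate_burdens <- function(cm, classification, min_reads = 4, k_max = 3,
                             seed = 1) {
  pass <- classification$status == "pass"
  snv <- pass & cm$variants$var_class == "SNV"
  ind <- pass & cm$variants$var_class == "indel"
  sam <- colnames(cm$NV)
  out <- lapply(seq_along(sam), function(s) {
    det <- cm$NV[, s] >= min_reads
    i_snv <- which(snv & det); i_ind <- which(ind & det)
    i_all <- c(i_snv, i_ind)
    row <- data.frame(sample = sam[s], raw_snv = length(i_snv),
                      raw_indel = length(i_ind), peak = NA_real_,
                      K = NA_integer_, S = NA_real_,
                      corrected_snv = NA_real_, corrected_indel = NA_real_,
                      median_vaf = NA_real_, monoclonal = NA,
                      excluded = TRUE, stringsAsFactors = FALSE)
    if (length(i_snv) < 10) return(row)
    # the peak estimate stabilizes long before 800 variants; cap the mixture
    # fit size (deterministic evenly spaced subsample)
    i_fit <- if (length(i_snv) > 800)
      i_snv[round(seq(1, length(i_snv), length.out = 800))] else i_snv
    fit <- fit_vaf_mixture(cm$NV[i_fit, s], cm$NR[i_fit, s], k_max = k_max,
                           min_reads = min_reads, seed = seed + s)
    peak <- fit$peaks[which.max(fit$weights)]
    sens <- estimate_sensitivity(cm$NR[i_all, s], peak, min_reads)
    cl <- median_vaf_and_clonality(cm$NV[i_all, s], cm$NR[i_all, s])
    row$peak <- peak; row$K <- fit$K; row$S <- sens$S
    bs <- corrected_burden(length(i_snv), sens$S, "SNV")
    bi <- corrected_burden(length(i_ind), sens$S, "indel")
    row$corrected_snv <- bs$corrected
    row$corrected_indel <- bi$corrected
    row$median_vaf <- cl$median_vaf
    row$monoclonal <- cl$monoclonal
    row$excluded <- bs$excluded
    row
  })
  do.call(rbind, out)
}
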