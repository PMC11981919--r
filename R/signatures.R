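# Mutational-signature analysis: catalog construction, reference-signature
# exposure fitting by EM (multinomial mixture), deconvolution of extracted
# spectra into reference combinations with a cosine-similarity acceptance
# rule, and per-signature fold increases in metaplastic glands.

#' Build a 96-channel SBS catalog
#'
#' Counts SNVs into pyrimidine-centred trinucleotide channels. Variants may
#' carry a precomputed `channel` column or `ref`/`alt`/`context` columns.
#'
#' @param variants data.frame of SNVs.
#' @return Object of class `mutation_catalog` (named integer vector of length
#'   96 with attributes `var_class = "SBS"` and `n_skipped`).
#' @export
build_sbs_catalog <- function(variants) {
  ch <- sbs96_channels()
  if (!nrow(variants)) return(.catalog(setNames(integer(96), ch), "SBS", 0))
  lab <- if ("channel" %in% names(variants) &&
             all(variants$channel %in% ch, na.rm = TRUE) &&
             !anyNA(variants$channel))
    variants$channel
  else {
    if (!all(c("ref", "alt", "context") %in% names(variants)))
      stop("build_sbs_catalog: need 'channel' or 'ref'/'alt'/'context'")
    sbs_channel(variants$ref, variants$alt, variants$context)
  }
  bad <- is.na(lab) | !(lab %in% ch)
  if (any(bad))
    warning("build_sbs_catalog: skipped ", sum(bad),
            " variant(s) with invalid context")
  counts <- table(factor(lab[!bad], levels = ch))
  .catalog(setNames(as.integer(counts), ch), "SBS", sum(bad))
}

#' Build an 83-channel ID catalog
#'
#' Counts indels into ID channels. Variants may carry a `channel` column or
#' homopolymer annotations (`indel_type` Del/Ins, `indel_base`, `hp_len`) for
#' 1-bp events; events that cannot be classified are counted into the
#' repeat-class channel of their length with repeat index 0 and reported in a
#' warning.
#'
#' @param variants data.frame of indels.
#' @return `mutation_catalog` of length 83, `var_class = "ID"`.
#' @export
build_id_catalog <- function(variants) {
  ch <- id83_channels()
  if (!nrow(variants)) return(.catalog(setNames(integer(83), ch), "ID", 0))
  lab <- rep(NA_character_, nrow(variants))
  if ("channel" %in% names(variants))
    lab <- ifelse(variants$channel %in% ch, variants$channel, NA)
  need <- is.na(lab)
  if (any(need) && all(c("indel_type", "indel_base", "hp_len") %in%
                       names(variants))) {
    lab[need] <- id_channel(variants$indel_type[need],
                            variants$indel_base[need],
                            variants$hp_len[need])
  }
  bad <- is.na(lab) | !(lab %in% ch)
  if (any(bad)) {
    fallback <- rep(NA_character_, sum(bad))
    if (all(c("ref", "alt") %in% names(variants))) {
      len <- abs(nchar(variants$ref[bad]) - nchar(variants$alt[bad]))
      type <- ifelse(nchar(variants$ref[bad]) > nchar(variants$alt[bad]),
                     "Del", "Ins")
      fallback <- ifelse(len >= 2, paste0(pmin(len, 5), ":", type, ":R:0"),
                         NA)
    }
    lab[bad] <- fallback
    warning("build_id_catalog: ", sum(bad), " indel(s) not classifiable",
            " from annotations; ", sum(!is.na(fallback)),
            " assigned to repeat catch-all channels")
  }
  ok <- !is.na(lab) & lab %in% ch
  counts <- table(factor(lab[ok], levels = ch))
  .catalog(setNames(as.integer(counts), ch), "ID", sum(!ok))
}

.catalog <- function(counts, var_class, n_skipped) {
  structure(counts, var_class = var_class, n_skipped = n_skipped,
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(attr(x, "var_class"), "catalog:", sum(x), "mutations in", length(x),
      "channels\n")
  top <- sort(x[x > 0], decreasing = TRUE)
  if (length(top)) print(utils::head(top, 5))
  invisible(x)
}

#' Fit reference-signature exposures by EM
#'
#' Maximum-likelihood weights of a multinomial mixture of reference signature
#' columns, fitted to an observed catalog. Iterates the EM multiplicative
#' update until the log-likelihood changes by less than `tol` (1e-8).
#'
#' @param catalog A `mutation_catalog` (or named counts matching the
#'   reference rows); total must be positive.
#' @param refs Reference signature matrix (channels x signatures, columns
#'   summing to 1), e.g. [synthetic_signatures()] or [read_signatures()].
#' @param subset Signature names to fit (default: all columns).
#' @param min_catalog Warn when the catalog holds fewer mutations (signature
#'   fits on small catalogs are unstable; 50).
#' @param tol,max_iter Convergence controls.
#' @return Object of class `exposure_vector`: named proportions summing to 1,
#'   with attributes `attributed` (proportions x total), `loglik`, `trace`,
#'   `niter`.
#' @export
fit_exposures_em <- function(catalog, refs, subset = colnames(refs),
                             min_catalog = 50, tol = 1e-8, max_iter = 5000) {
  if (!length(subset)) stop("fit_exposures_em: empty signature subset")
  if (!all(subset %in% colnames(refs)))
    stop("fit_exposures_em: unknown signatures: ",
         paste(setdiff(subset, colnames(refs)), collapse = ", "))
  x <- as.numeric(catalog)
  total <- sum(x)
  if (total <= 0) stop("fit_exposures_em: empty catalog")
  if (total < min_catalog)
    warning("fit_exposures_em: catalog holds ", total, " mutations (< ",
            min_catalog, "); exposures may be unstable")
  R <- refs[, subset, drop = FALSE]
  if (!is.null(names(catalog)) && !is.null(rownames(R))) {
    if (!all(names(catalog) %in% rownames(R)))
      stop("fit_exposures_em: catalog channels not in reference rows")
    R <- R[names(catalog), , drop = FALSE]
  }
  K <- ncol(R)
  w <- rep(1 / K, K)
  ll_prev <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    m <- as.vector(R %*% w)
    m[m < 1e-300] <- 1e-300
    ll <- sum(x * log(m))
    trace[it] <- ll
    if (it > 1 && abs(ll - ll_prev) < tol) break
    ll_prev <- ll
    w <- w * as.vector(crossprod(R, x / m)) / total
    w <- pmax(w, 0); w <- w / sum(w)
  }
  structure(setNames(w, subset), attributed = setNames(w * total, subset),
            loglik = ll, trace = trace, niter = it,
            class = "exposure_vector")
}

#' @export
print.exposure_vector <- function(x, ...) {
  cat("Signature exposures (total",
      format(sum(attr(x, "attributed"))), "mutations):\n")
  print(round(unclass(x)[order(-unclass(x))], 3))
  invisible(x)
}

#' Cosine similarity
#'
#' @param a,b Non-negative vectors of equal length.
#' @return `sum(a * b) / (|a| |b|)`; symmetric and scale-invariant.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Deconvolve an extracted signature into reference signatures
#'
#' Fits an EM mixture of reference columns to an extracted channel
#' distribution; the deconvolution is accepted when the reconstruction's
#' cosine similarity to the extracted signature reaches 0.90.
#'
#' @param extracted Channel distribution (sums to 1, same rows as `refs`).
#' @param refs Reference signature matrix.
#' @param subset Signature names to use.
#' @param accept_cosine Acceptance threshold (0.90).
#' @return Object of class `deconvolution_result`: `weights`, `cosine`,
#'   `accepted`, `reconstruction`.
#' @export
deconvolve_to_reference <- function(extracted, refs,
                                    subset = colnames(refs),
                                    accept_cosine = 0.90) {
  if (abs(sum(extracted) - 1) > 1e-6)
    stop("deconvolve_to_reference: extracted must sum to 1")
  w <- fit_exposures_em(extracted * 1e4, refs, subset = subset,
                        min_catalog = 0)
  recon <- as.vector(refs[, subset, drop = FALSE] %*% as.numeric(w))
  cs <- cosine_similarity(as.numeric(extracted), recon)
  structure(list(weights = setNames(as.numeric(w), subset), cosine = cs,
                 accepted = cs >= accept_cosine, reconstruction = recon),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("Deconvolution: cosine %.4f (%s)\n", x$cosine,
              if (x$accepted) "accepted" else "rejected"))
  print(round(x$weights[x$weights > 0.01], 3))
  invisible(x)
}

#' Merge SBS5/SBS40 exposures
#'
#' SBS5 and SBS40 (and its split components) have flat, hard-to-separate
#' profiles; downstream analyses report them combined as `SBS5/40`.
#'
#' @param exposures Named exposure vector.
#' @param members Signature names to merge.
#' @return Named vector with one combined `SBS5/40` entry.
#' @export
merge_sbs540 <- function(exposures,
                         members = c("SBS5", "SBS40", "SBS40a", "SBS40c")) {
  e <- unclass(exposures)
  m <- intersect(names(e), members)
  if (!length(m)) return(e)
  out <- c(e[setdiff(names(e), m)], "SBS5/40" = sum(e[m]))
  out
}

#' Convert extracted-signature exposures to reference exposures
#'
#' When de-novo extraction produced exposures to extracted signatures, and
#' each extracted signature was deconvolved into reference weights, reference
#' exposures follow by the matrix product (an interpretation of the
#' conversion "using the estimated signature proportions"): entry (sample,
#' reference) = sum over extracted signatures of exposure x weight.
#'
#' @param exposures Matrix samples x extracted signatures (rows sum to 1).
#' @param weights Matrix extracted signatures x reference signatures, each
#'   row the deconvolution weights of one extracted signature.
#' @return Matrix samples x reference signatures, rows renormalized to 1.
#' @export
convert_exposures <- function(exposures, weights) {
  exposures <- rbind(exposures)
  stopifnot(ncol(exposures) == nrow(weights))
  out <- exposures %*% as.matrix(weights)
  sweep(out, 1, rowSums(out), "/")
}

#' Per-signature fold increase over a donor baseline
#'
#' Three steps: (1) observed mutations per signature = exposure x corrected
#' burden; (2) expected = donor baseline exposure (mean over the donor's
#' non-metaplastic glands) x age-expected burden; (3) fold = observed /
#' expected.
#'
#' @param exposures Named exposure proportions of the sample.
#' @param corrected_burden Sensitivity-corrected burden of the sample.
#' @param baseline Named baseline proportions (same names; sums to 1).
#' @param expected_burden Age-expected burden (> 0).
#' @return Named folds. Signatures with zero baseline but non-zero observed
#'   count are `Inf` and flagged in attribute `infinite`.
#' @export
signature_fold_increase <- function(exposures, corrected_burden, baseline,
                                    expected_burden) {
  if (expected_burden <= 0)
    stop("signature_fold_increase: expected burden must be > 0")
  if (abs(sum(baseline) - 1) > 1e-6)
    stop("signature_fold_increase: baseline proportions must sum to 1")
  e <- unclass(exposures)
  sigs <- names(e)
  if (!all(sigs %in% names(baseline)))
    stop("signature_fold_increase: baseline missing signatures: ",
         paste(setdiff(sigs, names(baseline)), collapse = ", "))
  obs <- e * corrected_burden
  exp_ <- baseline[sigs] * expected_burden
  fold <- obs / exp_
  inf <- baseline[sigs] == 0 & obs > 0
  fold[baseline[sigs] == 0 & obs == 0] <- NA_real_
  structure(fold, infinite = unname(inf))
}

#' ID2/ID1 ratio
#'
#' Ratio of 1-bp T/A deletions (ID2-type) to 1-bp T/A insertions (ID1-type),
#' from an ID catalog (summing the `1:Del:T:*` vs `1:Ins:T:*` channels) or
#' from named exposure-attributed counts containing `ID1` and `ID2`.
#'
#' @param x A `mutation_catalog` (ID) or named numeric with `ID1`, `ID2`.
#' @return The ratio; `NA` (with warning) when the ID1 count is 0.
#' @export
id2_id1_ratio <- function(x) {
  if (inherits(x, "mutation_catalog")) {
    stopifnot(attr(x, "var_class") == "ID")
    id1 <- sum(x[grep("^1:Ins:T:", names(x))])
    id2 <- sum(x[grep("^1:Del:T:", names(x))])
  } else {
    id1 <- x[["ID1"]]; id2 <- x[["ID2"]]
  }
  if (id1 == 0) {
    warning("id2_id1_ratio: ID1 count is 0; ratio undefined")
    return(NA_real_)
  }
  unname(id2 / id1)
}
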