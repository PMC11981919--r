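# Fraction of epithelium colonized by driver-mutant clones: cell fractions
# from VAF x local ploidy, area-weighted aggregation over microdissections,
# and linear models for the roles of age, chronic inflammation and metaplasia.

DISRUPTING_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice")

#' Mutant cell fraction from VAF and local ploidy
#'
#' `min(1, vaf * local_ploidy)`; ploidy is 1 for sex chromosomes in male
#' donors, 2 otherwise. Values above 1 (noise) are capped, flagged in the
#' `capped` attribute.
#'
#' @param vaf VAF in \[0, 1\].
#' @param local_ploidy Copies at the locus (>= 1).
#' @return Cell fraction(s) in \[0, 1\].
#' @export
cell_fraction <- function(vaf, local_ploidy = 2) {
  stopifnot(all(vaf >= 0 & vaf <= 1), all(local_ploidy >= 1))
  raw <- vaf * local_ploidy
  structure(pmin(raw, 1), capped = raw > 1)
}

#' Flag driver mutations
#'
#' Disrupting mutations (missense, nonsense, frameshift, splice) in genes
#' under positive selection, plus hotspot matches in oncogenes.
#'
#' @param variants data.frame with `gene` and `consequence` columns (and
#'   `pos` if hotspots carry positions).
#' @param selection_genes Genes under selection (default the gastric set:
#'   ARID1A, ARID1B, ARID2, CTNNB1, EEF1A1, LIPF, KDM6A).
#' @param hotspots Optional data.frame of oncogene hotspots with `gene` and
#'   optionally `pos`; a missense match flags a driver.
#' @return `variants` with a logical `driver` column; unknown consequence
#'   terms warn and count as `"other"`.
#' @export
annotate_drivers <- function(variants, selection_genes = SELECTION_GENES,
                             hotspots = NULL) {
  cons <- variants$consequence
  known <- is.na(cons) | cons %in% c(DISRUPTING_CONSEQUENCES, "synonymous",
                                     "other")
  if (any(!known)) {
    warning("annotate_drivers: unknown consequence terms (",
            paste(unique(cons[!known]), collapse = ", "),
            "); treated as 'other'")
    cons[!known] <- "other"
  }
  drv <- !is.na(variants$gene) & variants$gene %in% selection_genes &
    cons %in% DISRUPTING_CONSEQUENCES
  if (!is.null(hotspots)) {
    hs <- variants$gene %in% hotspots$gene & cons %in% "missense"
    if (!is.null(hotspots$pos) && "pos" %in% names(variants))
      hs <- hs & paste(variants$gene, variants$pos) %in%
        paste(hotspots$gene, hotspots$pos)
    drv <- drv | hs
  }
  variants$driver <- drv
  variants
}

#' Fraction of sampled epithelium colonized by driver clones
#'
#' Per microdissection, the mutant cell fraction is derived from its driver
#' mutations (VAF x ploidy, capped at 1; multiple drivers combine by the
#' maximum by default, assuming nested clones, or by the capped sum).
#' The cohort estimate is `sum(area_i * fraction_i) / sum(area_i)`.
#' Contaminant (non-epithelial) reads depress VAFs, so the estimate is, if
#' anything, an underestimate.
#'
#' @param microdissections data.frame with `sample` and `area` (mm^2 > 0).
#' @param drivers data.frame with `sample`, `vaf`, `local_ploidy` (rows are
#'   driver mutations; samples may be absent = driver-free).
#' @param combine `"max"` or `"capped_sum"` for multiple drivers per sample.
#' @return List with `per_sample` (data.frame sample/area/mutant_fraction)
#'   and `cohort_fraction`.
#' @export
mutant_epithelium_fraction <- function(microdissections, drivers,
                                       combine = c("max", "capped_sum")) {
  combine <- match.arg(combine)
  stopifnot(all(c("sample", "area") %in% names(microdissections)))
  if (any(microdissections$area <= 0))
    stop("mutant_epithelium_fraction: areas must be > 0")
  if (sum(microdissections$area) <= 0)
    stop("mutant_epithelium_fraction: zero total area")
  frac <- setNames(numeric(nrow(microdissections)),
                   microdissections$sample)
  if (nrow(drivers)) {
    cf <- cell_fraction(drivers$vaf,
                        drivers$local_ploidy %||% 2)
    agg <- tapply(as.numeric(cf), drivers$sample,
                  if (combine == "max") max else function(x) min(1, sum(x)))
    hit <- names(agg)[names(agg) %in% names(frac)]
    frac[hit] <- agg[hit]
  }
  per_sample <- data.frame(sample = microdissections$sample,
                           area = microdissections$area,
                           mutant_fraction = unname(frac),
                           stringsAsFactors = FALSE)
  list(per_sample = per_sample,
       cohort_fraction = sum(per_sample$area * per_sample$mutant_fraction) /
         sum(per_sample$area))
}

#' Linear models for the driver-mutant proportion
#'
#' Fits `proportion ~ age`, `~ age + ci_grade` and `~ age + im_proportion`
#' on donor-level data and compares the extended models against the age-only
#' model by F-test (ANOVA).
#'
#' @param data data.frame with one row per donor: `proportion`, `age`,
#'   `ci_grade` (factor/character), `im_proportion` (numeric). Constant
#'   covariates are dropped with a warning.
#' @return List with `fits` (named lm objects) and `comparisons` (data.frame
#'   of model pairs with F and p).
#' @export
fit_mutant_proportion_models <- function(data) {
  stopifnot(all(c("proportion", "age") %in% names(data)))
  if (length(unique(data$age)) < 2) stop("age is constant")
  if (nrow(data) < 3) stop("need at least 3 donors")
  forms <- list(age = proportion ~ age)
  if (!is.null(data$ci_grade)) {
    if (length(unique(data$ci_grade)) > 1)
      forms$`age+ci` <- proportion ~ age + ci_grade
    else warning("ci_grade is constant; model dropped")
  }
  if (!is.null(data$im_proportion)) {
    if (length(unique(data$im_proportion)) > 1)
      forms$`age+im` <- proportion ~ age + im_proportion
    else warning("im_proportion is constant; model dropped")
  }
  fits <- lapply(forms, lm, data = data)
  cmp <- lapply(setdiff(names(fits), "age"), function(nm) {
    a <- anova(fits$age, fits[[nm]])
    data.frame(small = "age", large = nm, F = a$F[2], p = a$`Pr(>F)`[2],
               stringsAsFactors = FALSE)
  })
  list(fits = fits,
       comparisons = if (length(cmp)) do.call(rbind, cmp) else NULL)
}
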