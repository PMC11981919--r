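# Mutation-rate models: linear mixed-effects fits of burden against age with
# a donor random intercept, nested-model comparison by likelihood ratio, and
# observed/expected burden fold changes.

RATE_FORMULAS <- c(
  "age"          = "burden ~ age + (1 | donor)",
  "age+ci"       = "burden ~ age + ci + (1 | donor)",
  "age+im"       = "burden ~ age + im + (1 | donor)",
  "age+im+ci"    = "burden ~ age + im + ci + (1 | donor)",
  "age:site+im"  = "burden ~ age:site + im + (1 | donor)"
)

#' Fit a mixed-effects mutation-rate model
#'
#' `Burden ~ Age + (1 | Donor)` and its extensions with chronic-inflammation
#' (CI, coded absent/mild vs moderate/severe) and intestinal-metaplasia (IM)
#' terms, estimated by maximum likelihood (so that nested fits can be compared
#' by likelihood ratio).
#'
#' @param burden Corrected mutation burdens (one per sample).
#' @param age Donor age per sample, years.
#' @param donor Donor id per sample (random intercept grouping).
#' @param covariates Optional data.frame with `ci` (logical or grade labels
#'   in absent/mild/moderate/severe, dichotomized), `im` (logical) and `site`.
#' @param formula One of `"age"`, `"age+ci"`, `"age+im"`, `"age+im+ci"`,
#'   `"age:site+im"`.
#' @return Object of class `rate_model_fit`: `slope` (mutations/year), `ci`
#'   (95 % Wald interval), `intercept`, `donor_sd`, `residual_sd`, `loglik`,
#'   `npar`, `formula`, and the underlying `lme4` fit.
#' @export
fit_burden_rate_model <- function(burden, age, donor, covariates = NULL,
                                  formula = "age") {
  formula <- match.arg(formula, names(RATE_FORMULAS))
  d <- data.frame(burden = burden, age = age, donor = factor(donor))
  if (!is.null(covariates)) {
    if (!is.null(covariates$ci)) {
      ci <- covariates$ci
      if (!is.logical(ci)) ci <- ci %in% c("moderate", "severe")
      d$ci <- ci
    }
    if (!is.null(covariates$im)) d$im <- as.logical(covariates$im)
    if (!is.null(covariates$site)) d$site <- factor(covariates$site)
  }
  need <- setdiff(all.vars(as.formula(RATE_FORMULAS[[formula]])), names(d))
  if (length(need))
    stop("fit_burden_rate_model: covariates missing for terms: ",
         paste(need, collapse = ", "))
  keep <- !is.na(d$burden)
  d <- d[keep, , drop = FALSE]
  if (length(unique(d$donor)) < 2)
    stop("fit_burden_rate_model: need at least 2 donors")
  if (nrow(d) < 3) stop("fit_burden_rate_model: need at least 3 samples")

  ctrl <- lme4::lmerControl(
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- tryCatch(
    lme4::lmer(as.formula(RATE_FORMULAS[[formula]]), data = d, REML = FALSE,
               control = ctrl),
    error = function(e) {
      if (grepl("rank deficient|collinear|singular fit", conditionMessage(e)))
        stop("fit_burden_rate_model: singular design (collinear terms) in '",
             formula, "': ", conditionMessage(e), call. = FALSE)
      stop(e)
    })
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  slope <- unname(fe["age"])
  slope_se <- unname(se[names(fe) == "age"])
  if (!"age" %in% names(fe)) { slope <- NA_real_; slope_se <- NA_real_ }
  structure(list(
    slope = slope,
    ci = if (!is.na(slope)) slope + c(-1, 1) * 1.96 * slope_se else
      c(NA_real_, NA_real_),
    intercept = unname(fe["(Intercept)"]),
    fixef = fe,
    donor_sd = vc$sdcor[vc$grp == "donor"][1],
    residual_sd = vc$sdcor[vc$grp == "Residual"][1],
    loglik = as.numeric(logLik(fit)),
    npar = attr(logLik(fit), "df"),
    formula = formula,
    n = nrow(d),
    fit = fit), class = "rate_model_fit")
}

#' @export
print.rate_model_fit <- function(x, ...) {
  cat("Mutation-rate mixed model [", x$formula, "], n =", x$n, "\n")
  cat(sprintf("  slope %.2f mutations/year (95%% CI %.2f-%.2f)\n",
              x$slope, x$ci[1], x$ci[2]))
  cat(sprintf("  donor SD %.2f, residual SD %.2f, loglik %.1f\n",
              x$donor_sd, x$residual_sd, x$loglik))
  invisible(x)
}

#' Likelihood-ratio comparison of nested rate models
#'
#' `2 * (loglik_large - loglik_small)` referred to a chi-square with degrees
#' of freedom equal to the difference in parameter count. Models must be
#' nested (the smaller model's fixed terms a subset of the larger's) and
#' fitted by maximum likelihood on identical data.
#'
#' @param fit_small,fit_large `rate_model_fit` objects.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
compare_models <- function(fit_small, fit_large) {
  terms_of <- function(f) {
    tt <- attr(stats::terms(as.formula(RATE_FORMULAS[[f$formula]])),
               "term.labels")
    setdiff(tt, grep("\\|", tt, value = TRUE))
  }
  ts <- terms_of(fit_small); tl <- terms_of(fit_large)
  if (!all(ts %in% tl))
    stop("compare_models: models are not nested (",
         paste(setdiff(ts, tl), collapse = ", "), " not in larger model)")
  if (fit_small$n != fit_large$n)
    stop("compare_models: models were fitted on different data")
  stat <- max(0, 2 * (fit_large$loglik - fit_small$loglik))
  df <- fit_large$npar - fit_small$npar
  p <- if (df <= 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

#' Observed/expected burden fold change
#'
#' Ratio of a sample's corrected burden to the burden expected at its age
#' under a rate model fitted on non-metaplastic glands (fixed effects only).
#'
#' @param corrected Corrected burden(s).
#' @param age Age(s), years.
#' @param rate_model A `rate_model_fit` (age model).
#' @return Fold change(s); `NA` with a warning where the expected burden is
#'   not positive.
#' @export
burden_fold_change <- function(corrected, age, rate_model) {
  expected <- rate_model$intercept + rate_model$slope * age
  bad <- expected <= 0
  if (any(bad, na.rm = TRUE))
    warning("burden_fold_change: non-positive expected burden for ",
            sum(bad), " sample(s); fold undefined")
  fold <- corrected / expected
  fold[bad] <- NA_real_
  fold
}
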