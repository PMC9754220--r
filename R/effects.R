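# Mixed-effects estimation of age and sex effects: eye-level observations,
# subject random intercepts, AIC selection between linear and quadratic age
# models, combined 40-80 age coefficients, young-group percent transforms,
# multiplicity control and marginal R-squared.

# Build the model frame for one parameter. Age is centered at the reference
# age (40) before fitting to de-correlate the linear and quadratic terms;
# reported coefficients are mapped back where needed.
effects_frame <- function(table, parameter) {
  d <- table[table$parameter == parameter, ]
  if (!nrow(d)) stop("parameter not found in table: ", parameter)
  data.frame(
    value = d$value,
    is_male = as.numeric(d$sex == "male"),
    age_c = d$age_years - REF_AGE,
    age_c2 = (d$age_years - REF_AGE)^2,
    scan_focus = d$scan_focus_D,
    subject_id = d$subject_id,
    age_years = d$age_years,
    sex = d$sex,
    stringsAsFactors = FALSE
  )
}

#' Fit one candidate mixed model for a parameter
#'
#' Maximum-likelihood fit (REML off, so models with different fixed-effect
#' structures are comparable by AIC and likelihood ratio) of
#' `value ~ is_male + age + (age^2) + scan_focus + (1 | subject)` with age
#' centered at 40 years.
#'
#' @param table long parameter table (see [simulate_parameter_table()]).
#' @param parameter parameter name to model.
#' @param quadratic include the quadratic age term?
#' @param age_terms `"both"` (default per `quadratic`), or `"none"` for the
#'   no-age reference model used by the combined age test.
#' @return a fitted `lmerMod` object.
#' @export
fit_candidate <- function(table, parameter, quadratic = FALSE,
                          age_terms = if (quadratic) "quadratic" else
                            "linear") {
  d <- effects_frame(table, parameter)
  if (length(unique(d$subject_id)) < 2L) {
    stop("need at least 2 subjects")
  }
  form <- switch(age_terms,
    none = value ~ is_male + scan_focus + (1 | subject_id),
    linear = value ~ is_male + age_c + scan_focus + (1 | subject_id),
    quadratic = value ~ is_male + age_c + age_c2 + scan_focus +
      (1 | subject_id),
    stop("unknown age_terms: ", age_terms)
  )
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
  fit
}

#' Select the age model by AIC
#'
#' Fits the linear and quadratic age models by maximum likelihood and keeps
#' the one with the lower AIC; exact ties prefer the linear model.
#'
#' @inheritParams fit_candidate
#' @return list with `fit` (the selected `lmerMod`), `model_form`
#'   (`"linear"`/`"quadratic"`), `aic_linear`, `aic_quadratic`.
#' @export
select_age_model <- function(table, parameter) {
  lin <- try(fit_candidate(table, parameter, quadratic = FALSE),
             silent = TRUE)
  quad <- try(fit_candidate(table, parameter, quadratic = TRUE),
              silent = TRUE)
  if (inherits(lin, "try-error") && inherits(quad, "try-error")) {
    stop("both age models failed for ", parameter)
  }
  if (inherits(quad, "try-error")) {
    warning("quadratic fit failed for ", parameter, "; using linear")
    return(list(fit = lin, model_form = "linear",
                aic_linear = stats::AIC(lin), aic_quadratic = NA_real_))
  }
  if (inherits(lin, "try-error")) {
    warning("linear fit failed for ", parameter, "; using quadratic")
    return(list(fit = quad, model_form = "quadratic",
                aic_linear = NA_real_, aic_quadratic = stats::AIC(quad)))
  }
  a_lin <- stats::AIC(lin)
  a_quad <- stats::AIC(quad)
  if (a_quad < a_lin) {
    list(fit = quad, model_form = "quadratic",
         aic_linear = a_lin, aic_quadratic = a_quad)
  } else {
    list(fit = lin, model_form = "linear",
         aic_linear = a_lin, aic_quadratic = a_quad)
  }
}

#' Combined 40-80 age effect
#'
#' The single age coefficient reported for both model forms: the mean
#' yearly change between ages 40 and 80, `(yhat(80) - yhat(40)) / 40 =
#' b1 + 40 * b2` in the age-centered parameterization, reported per decade
#' (x10). The CI is Wald with normal quantiles on the variance of the
#' linear combination.
#'
#' @param fit a fitted `lmerMod` from [fit_candidate()].
#' @param level confidence level.
#' @return list with `estimate_per10y`, `ci_per10y` (length 2), `se_per10y`.
#' @export
combined_age_effect <- function(fit, level = 0.95) {
  beta <- lme4::fixef(fit)
  V <- safe_vcov(fit)
  if (!"age_c" %in% names(beta)) {
    return(list(estimate_per10y = 0, ci_per10y = c(0, 0), se_per10y = 0))
  }
  w <- stats::setNames(numeric(length(beta)), names(beta))
  w["age_c"] <- 1
  if ("age_c2" %in% names(beta)) w["age_c2"] <- 40
  est <- sum(w * beta)
  se <- sqrt(drop(t(w) %*% V %*% w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate_per10y = 10 * est,
       ci_per10y = 10 * c(est - z * se, est + z * se),
       se_per10y = 10 * se)
}

#' Combined age p-value
#'
#' When the selected model is quadratic: a 2-df likelihood-ratio chi-square
#' comparing the no-age reference model with the quadratic model (both ML),
#' giving a single p-value for the combined linear + quadratic age effect.
#' When the selected model is linear: the Wald p-value of the linear age
#' coefficient.
#'
#' @param table,parameter as in [fit_candidate()].
#' @param selected the [select_age_model()] result.
#' @return p-value.
#' @export
age_pvalue <- function(table, parameter, selected) {
  if (selected$model_form == "quadratic") {
    ref <- fit_candidate(table, parameter, age_terms = "none")
    ll0 <- as.numeric(stats::logLik(ref))
    ll1 <- as.numeric(stats::logLik(selected$fit))
    stat <- max(0, 2 * (ll1 - ll0))
    stats::pchisq(stat, df = 2, lower.tail = FALSE)
  } else {
    wald_p(selected$fit, "age_c")
  }
}

# Variance-covariance of the fixed effects, robust to degenerate fits
# (boundary variance estimates can make lme4's vcov computation fail); in
# that case an all-NA matrix with the right dimnames is returned and Wald
# quantities propagate as NA.
safe_vcov <- function(fit) {
  beta <- lme4::fixef(fit)
  V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                error = function(e) NULL)
  if (is.null(V) || !all(dim(V) == length(beta))) {
    V <- matrix(NA_real_, length(beta), length(beta),
                dimnames = list(names(beta), names(beta)))
  }
  if (is.null(dimnames(V))) dimnames(V) <- list(names(beta), names(beta))
  V
}

wald_p <- function(fit, term) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(safe_vcov(fit)))[term]
  2 * stats::pnorm(-abs(beta[[term]] / se))
}

#' Young-group percent transform
#'
#' Converts absolute effect estimates to percent of the young-group mean:
#' age effects are divided by the mean parameter value among eyes of
#' subjects aged <= 40, sex effects by the mean among young females; CIs
#' are rescaled by the same scalar.
#'
#' @param table long parameter table.
#' @param parameter parameter name.
#' @return list with `young_mean` and `young_female_mean` (um).
#' @export
young_reference_means <- function(table, parameter) {
  d <- table[table$parameter == parameter, ]
  young <- d$age_years <= 40
  if (!any(young)) stop("no subjects aged <= 40 for percent transform")
  yf <- young & d$sex == "female"
  if (!any(yf)) stop("no young female subjects for percent transform")
  list(young_mean = mean(d$value[young]),
       young_female_mean = mean(d$value[yf]))
}

#' Multiplicity adjustment
#'
#' Holm step-down family-wise correction for the whole-macula families and
#' Benjamini-Hochberg step-up FDR for the sector maps; returns adjusted
#' p-values and significance flags at `alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"holm"` or `"bh"`.
#' @param alpha significance level.
#' @return list with `adjusted` and `significant`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = if (method == "holm") "holm" else "BH")
  list(adjusted = adj, significant = adj < alpha)
}

#' Marginal R-squared of a mixed model
#'
#' The share of variance explained by the fixed effects alone:
#' `var(fixed predictions) / (var(fixed) + var(random intercept) +
#' var(residual)) * 100`.
#'
#' @param fit a fitted `lmerMod`.
#' @return marginal R-squared in percent.
#' @export
marginal_r2 <- function(fit) {
  X <- lme4::getME(fit, "X")
  pred <- drop(X %*% lme4::fixef(fit))
  vf <- mean((pred - mean(pred))^2)
  vc <- lme4::VarCorr(fit)
  vr <- as.numeric(vc$subject_id[1])
  ve <- attr(vc, "sc")^2
  tot <- vf + vr + ve
  if (tot <= 0) stop("zero total variance")
  100 * vf / tot
}

#' Estimate age and sex effects for a set of parameters
#'
#' The full per-parameter analysis: AIC age-model selection, combined
#' 40-80 age effect per decade with Wald CI, combined age p-value, sex
#' effect (male - female) with Wald CI and p, percent transforms against
#' the young group, marginal R-squared, and family-wise multiplicity
#' adjustment over all age and sex tests of the family.
#'
#' @param table long parameter table.
#' @param parameters parameters to analyze (default: all in the table, in
#'   first-appearance order).
#' @param family_method `"holm"` (whole-macula families) or `"bh"`
#'   (sector-map families).
#' @param alpha significance level for corrected flags.
#' @return data.frame with one row per parameter mirroring the normative
#'   effect-table layout (absolute and percent coefficients, CIs,
#'   p-values, corrected flags, marginal R-squared and AICs).
#' @export
estimate_effects <- function(table, parameters = unique(table$parameter),
                             family_method = c("holm", "bh"),
                             alpha = 0.05) {
  family_method <- match.arg(family_method)
  rows <- lapply(parameters, function(p) {
    sel <- select_age_model(table, p)
    fit <- sel$fit
    beta <- lme4::fixef(fit)
    V <- safe_vcov(fit)
    age <- combined_age_effect(fit)
    p_age <- age_pvalue(table, p, sel)
    b_sex <- beta[["is_male"]]
    se_sex <- sqrt(V["is_male", "is_male"])
    z <- stats::qnorm(0.975)
    refs <- young_reference_means(table, p)
    pct_age <- 100 / refs$young_mean
    pct_sex <- 100 / refs$young_female_mean
    data.frame(
      parameter = p, model_form = sel$model_form,
      aic_linear = sel$aic_linear, aic_quadratic = sel$aic_quadratic,
      beta_age_abs_per10y = age$estimate_per10y,
      beta_age_abs_lo = age$ci_per10y[1], beta_age_abs_hi = age$ci_per10y[2],
      beta_age_pct_per10y = age$estimate_per10y * pct_age,
      beta_age_pct_lo = age$ci_per10y[1] * pct_age,
      beta_age_pct_hi = age$ci_per10y[2] * pct_age,
      p_age = p_age,
      beta_sex_abs = b_sex,
      beta_sex_abs_lo = b_sex - z * se_sex,
      beta_sex_abs_hi = b_sex + z * se_sex,
      beta_sex_pct = b_sex * pct_sex,
      beta_sex_pct_lo = (b_sex - z * se_sex) * pct_sex,
      beta_sex_pct_hi = (b_sex + z * se_sex) * pct_sex,
      p_sex = wald_p(fit, "is_male"),
      beta_sf = beta[["scan_focus"]],
      r2_marginal_pct = marginal_r2(fit),
      young_mean = refs$young_mean,
      young_female_mean = refs$young_female_mean,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  fam <- adjust_pvalues(c(out$p_age, out$p_sex), method = family_method,
                        alpha = alpha)
  n <- nrow(out)
  out$p_age_adj <- fam$adjusted[seq_len(n)]
  out$p_sex_adj <- fam$adjusted[n + seq_len(n)]
  out$sig_age_corrected <- fam$significant[seq_len(n)]
  out$sig_sex_corrected <- fam$significant[n + seq_len(n)]
  out$n_tests_family <- 2L * n
  rownames(out) <- NULL
  out
}

#' Percent transform of an absolute effect estimate
#'
#' Scales an absolute estimate (and optionally its CI bounds) to percent of
#' a reference mean. Percent values are invariant under a global rescaling
#' of the parameter's units (the reference rescales identically).
#'
#' @param estimate absolute effect estimate.
#' @param reference_mean young-group reference mean (same units).
#' @param ci optional CI bounds to rescale.
#' @return list with `percent` and (if given) `ci_percent`.
#' @export
percent_transform <- function(estimate, reference_mean, ci = NULL) {
  if (!is.finite(reference_mean) || reference_mean == 0) {
    stop("reference mean must be non-zero and finite")
  }
  out <- list(percent = 100 * estimate / reference_mean)
  if (!is.null(ci)) out$ci_percent <- 100 * ci / reference_mean
  out
}
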