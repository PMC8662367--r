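# Exposure-outcome association models with tiered covariate adjustment.
#
# Three nested model tiers: a basic model (child sex and age at outcome), a
# confounder model (adding maternal age, ethnicity, prepregnancy BMI,
# education, household income, smoking, alcohol and folic acid use), and a
# BMI model (adding the child's age- and sex-adjusted BMI SD score at the
# outcome visit). Estimates are linear regression coefficients with 95% CIs;
# significance is two-sided p < .05 with no multiplicity correction.

#' Covariate sets for the three model tiers
#'
#' @param tier One of `"basic"`, `"confounder"`, `"bmi"`.
#' @param basic Covariates of the basic tier.
#' @param confounders Covariates added by the confounder tier.
#' @param bmi Covariates added by the BMI tier.
#' @return Character vector of covariate names (a superset chain:
#'   basic, then + confounders, then + child BMI).
#' @export
tier_covariates <- function(tier = c("basic", "confounder", "bmi"),
                            basic = c("sex", "age_mri"),
                            confounders = c("m_age", "ethnicity", "m_bmi",
                                            "education", "income", "smoking",
                                            "alcohol", "folic"),
                            bmi = "child_bmi_z") {
  tier <- match.arg(tier)
  switch(tier,
         basic = basic,
         confounder = c(basic, confounders),
         bmi = c(basic, confounders, bmi))
}

build_assoc_frame <- function(data, outcome, exposure, covariates,
                              icv_adjust, extra = character(0)) {
  vars <- unique(c(outcome, exposure, covariates,
                   if (icv_adjust) "icv", extra))
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop_ec("configuration_error", "variable(s) not in data: %s",
            paste(miss, collapse = ", "))
  }
  d <- data[, vars, drop = FALSE]
  d[stats::complete.cases(d), , drop = FALSE]
}

#' Fit one exposure-outcome association model
#'
#' Ordinary least squares of `outcome` on `exposure` plus the covariate set.
#' Categorical exposures are expanded to indicator contrasts against the
#' stated reference level and yield one result row per non-reference level.
#' CIs use the normal approximation (estimate +/- 1.96 se); p-values are the
#' usual two-sided t tests.
#'
#' @param data Analysis table.
#' @param outcome Outcome column name (volume in cm^3 or head circumference
#'   in cm).
#' @param exposure Exposure column name; continuous or categorical.
#' @param covariates Character vector of covariate column names (see
#'   [tier_covariates()]).
#' @param reference Reference level for a categorical exposure; default is
#'   the factor's first level.
#' @param icv_adjust Additionally adjust for intracranial volume (column
#'   `icv`)? Used for post hoc subcortical analyses.
#' @param tier Tier label carried into the result (bookkeeping only).
#' @return Data frame of class `association_result`: one row per estimate,
#'   with `outcome`, `exposure`, `level`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `p`, `n`, `tier`, `pooled`.
#' @export
fit_association <- function(data, outcome, exposure,
                            covariates = character(0), reference = NULL,
                            icv_adjust = FALSE, tier = NA_character_) {
  d <- build_assoc_frame(data, outcome, exposure, covariates, icv_adjust)
  categorical <- is.factor(d[[exposure]]) || is.character(d[[exposure]])
  if (categorical) {
    d[[exposure]] <- factor(d[[exposure]])
    d[[exposure]] <- droplevels(d[[exposure]])
    if (!is.null(reference)) {
      if (!reference %in% levels(d[[exposure]])) {
        stop_ec("configuration_error", "reference level '%s' not found", reference)
      }
      d[[exposure]] <- stats::relevel(d[[exposure]], ref = reference)
    }
    if (nlevels(d[[exposure]]) < 2) {
      stop_ec("collinearity_error", "exposure '%s' has a single level", exposure)
    }
  } else if (stats::var(d[[exposure]]) == 0) {
    stop_ec("collinearity_error", "exposure '%s' is constant", exposure)
  }
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covariates),
                 if (icv_adjust) "icv"), collapse = " + ")
  p_par <- length(covariates) + (if (categorical) nlevels(d[[exposure]]) - 1 else 1) +
    icv_adjust + 1
  if (nrow(d) <= p_par + 10) {
    stop_ec("insufficient_data", "n = %d too small for %d parameters",
            nrow(d), p_par)
  }
  fit <- stats::lm(stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs)), data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop_ec("collinearity_error", "rank-deficient design for exposure '%s'",
            exposure)
  }
  sm <- summary(fit)$coefficients
  terms_wanted <- if (categorical) {
    paste0(sprintf("`%s`", exposure), levels(d[[exposure]])[-1])
  } else {
    sprintf("`%s`", exposure)
  }
  # lm backtick handling: names may come out without backticks
  rn <- rownames(sm)
  pick <- function(term) {
    stripped <- gsub("`", "", term, fixed = TRUE)
    i <- match(term, rn)
    if (is.na(i)) i <- match(stripped, rn)
    if (is.na(i)) stop_ec("configuration_error", "term '%s' not in fit", stripped)
    i
  }
  idx <- vapply(terms_wanted, pick, integer(1))
  est <- sm[idx, 1]; se <- sm[idx, 2]; pv <- sm[idx, 4]
  res <- data.frame(
    outcome = outcome, exposure = exposure,
    level = if (categorical) levels(d[[exposure]])[-1] else NA_character_,
    estimate = unname(est), se = unname(se),
    ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
    p = unname(pv), n = nrow(d), tier = tier, pooled = FALSE,
    stringsAsFactors = FALSE)
  if (categorical) {
    refrow <- data.frame(outcome = outcome, exposure = exposure,
                         level = levels(d[[exposure]])[1],
                         estimate = NA_real_, se = NA_real_,
                         ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                         n = nrow(d), tier = tier, pooled = FALSE,
                         stringsAsFactors = FALSE)
    res <- rbind(refrow, res)
  }
  class(res) <- c("association_result", class(res))
  res
}

#' Test an exposure-by-sex interaction
#'
#' Adds an exposure-by-sex product term to the tier model and reports the
#' Wald test (single-df for continuous exposures; an F test comparing nested
#' models for categorical exposures).
#'
#' @inheritParams fit_association
#' @param sex_var Name of the sex column.
#' @return List with `estimate`, `se`, `p` (estimate/se are `NA` for
#'   categorical exposures, where `p` is the joint F-test p-value).
#' @export
test_sex_interaction <- function(data, outcome, exposure,
                                 covariates = character(0),
                                 sex_var = "sex", icv_adjust = FALSE) {
  covariates <- union(covariates, sex_var)
  d <- build_assoc_frame(data, outcome, exposure, covariates, icv_adjust)
  if (length(unique(d[[sex_var]])) < 2) {
    stop_ec("degenerate_design", "only one sex present")
  }
  d[[sex_var]] <- factor(d[[sex_var]])
  categorical <- is.factor(d[[exposure]]) || is.character(d[[exposure]])
  if (categorical) d[[exposure]] <- factor(d[[exposure]])
  base_rhs <- paste(c(sprintf("`%s`", exposure),
                      sprintf("`%s`", covariates),
                      if (icv_adjust) "icv"), collapse = " + ")
  f0 <- stats::as.formula(sprintf("`%s` ~ %s", outcome, base_rhs))
  f1 <- stats::as.formula(sprintf("`%s` ~ %s + `%s`:`%s`", outcome, base_rhs,
                                  exposure, sex_var))
  m0 <- stats::lm(f0, data = d)
  m1 <- stats::lm(f1, data = d)
  if (categorical) {
    p <- stats::anova(m0, m1)[2, "Pr(>F)"]
    return(list(estimate = NA_real_, se = NA_real_, p = p))
  }
  sm <- summary(m1)$coefficients
  rn <- rownames(sm)
  i <- grep(":", rn, fixed = TRUE)
  if (length(i) != 1) stop_ec("configuration_error", "interaction term not identified")
  list(estimate = unname(sm[i, 1]), se = unname(sm[i, 2]), p = unname(sm[i, 4]))
}

#' Test departure from linearity with a spline nested-model F test
#'
#' Compares the tier's linear model against the same model with the exposure
#' replaced by a natural cubic spline (default 3 knots, i.e. 2 additional
#' df), via the standard F test for nested OLS models. A deterministic
#' substitute for a penalized additive-model check.
#'
#' @inheritParams fit_association
#' @param n_knots Number of spline knots.
#' @return List with `p` (departure-from-linearity p-value), `df` (extra
#'   spline df) and `n`.
#' @export
test_nonlinearity <- function(data, outcome, exposure,
                              covariates = character(0), n_knots = 3,
                              icv_adjust = FALSE) {
  d <- build_assoc_frame(data, outcome, exposure, covariates, icv_adjust)
  x <- d[[exposure]]
  if (!is.numeric(x)) {
    stop_ec("configuration_error", "nonlinearity test needs a continuous exposure")
  }
  if (length(unique(x)) < n_knots + 2) {
    stop_ec("insufficient_variation",
            "exposure has %d distinct values; need at least %d",
            length(unique(x)), n_knots + 2)
  }
  cov_rhs <- paste(c(sprintf("`%s`", covariates), if (icv_adjust) "icv"),
                   collapse = " + ")
  tail_rhs <- if (nzchar(cov_rhs)) paste0(" + ", cov_rhs) else ""
  f0 <- stats::as.formula(sprintf("`%s` ~ `%s`%s", outcome, exposure, tail_rhs))
  f1 <- stats::as.formula(sprintf("`%s` ~ splines::ns(`%s`, df = %d)%s",
                                  outcome, exposure, n_knots - 1, tail_rhs))
  m0 <- stats::lm(f0, data = d)
  m1 <- stats::lm(f1, data = d)
  a <- stats::anova(m0, m1)
  list(p = a[2, "Pr(>F)"], df = a[2, "Df"], n = nrow(d))
}

#' Run a table of association models
#'
#' Fits every exposure-outcome pair of a recipe at one tier and returns the
#' stacked results in deterministic order (exposures in given order, outcomes
#' within exposure). Reference levels of categorical exposures appear as
#' explicit `[Reference]` rows when formatted.
#'
#' @param data Analysis table (or a list of multiply imputed tables, in
#'   which case estimates are pooled by Rubin's rules).
#' @param outcomes Character vector of outcome columns.
#' @param exposures Character vector of exposure columns, or a named list
#'   whose elements optionally carry a `reference` attribute.
#' @param covariates Covariates (see [tier_covariates()]).
#' @param references Named character vector mapping categorical exposures to
#'   reference levels.
#' @param tier Tier label.
#' @param icv_adjust Adjust for intracranial volume.
#' @return An `association_result` data frame.
#' @export
run_table <- function(data, outcomes, exposures, covariates = character(0),
                      references = NULL, tier = NA_character_,
                      icv_adjust = FALSE) {
  imputed <- is.list(data) && !is.data.frame(data)
  rows <- list()
  for (ex in exposures) {
    ref <- if (!is.null(references) && ex %in% names(references))
      references[[ex]] else NULL
    for (oc in outcomes) {
      rows[[length(rows) + 1L]] <- if (imputed) {
        fit_association_pooled(data, oc, ex, covariates = covariates,
                               reference = ref, icv_adjust = icv_adjust,
                               tier = tier)
      } else {
        fit_association(data, oc, ex, covariates = covariates,
                        reference = ref, icv_adjust = icv_adjust, tier = tier)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Format an association table for reporting
#'
#' Renders `estimate (ci_lo to ci_hi)` with significance markers `*`
#' (p < .05) and `**` (p < .01); reference rows render as `[Reference]`.
#'
#' @param res An `association_result`.
#' @param digits Decimal places.
#' @return Character data frame ready for printing or writing.
#' @export
format_assoc_table <- function(res, digits = 1) {
  fmt <- function(e, lo, hi, p) {
    if (is.na(e)) return("[Reference]")
    stars <- if (!is.na(p) && p < 0.01) "**" else if (!is.na(p) && p < 0.05) "*" else ""
    sprintf("%.*f (%.*f to %.*f)%s", digits, e, digits, lo, digits, hi, stars)
  }
  data.frame(outcome = res$outcome, exposure = res$exposure,
             level = ifelse(is.na(res$level), "", as.character(res$level)),
             n = res$n, tier = res$tier,
             difference = mapply(fmt, res$estimate, res$ci_lo, res$ci_hi, res$p),
             stringsAsFactors = FALSE)
}
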