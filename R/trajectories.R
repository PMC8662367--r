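# Infant growth-trajectory models.
#
# Reed1 weight curve, fitted per sex on all weights from birth to 3 years
# (birth weight mapped to a small positive age because ln t and 1/t are
# singular at t = 0):
#   W(t) = a + b t + c ln t + d / t,   t in years, W in kg.
# Velocity v(t) = b + c/t - d/t^2 has an interior maximum iff c > 0 and
# d > 0, at t* = 2d/c, with peak weight velocity PWV = b + c^2/(4d).
#
# Adiposity peak: cubic mixed model on log BMI over 14 days - 1.5 years,
# adjusted for sex; the subject-level peak is the in-window stationary point
# of the cubic with negative second derivative.

reed1_basis <- function(t) {
  cbind(t = t, lnt = log(t), invt = 1 / t)
}

#' Closed-form peak weight velocity from Reed1 coefficients
#'
#' The weight velocity \eqn{v(t) = b + c/t - d/t^2} attains an interior
#' maximum at \eqn{t^* = 2d/c} with \eqn{PWV = b + c^2/(4d)}, provided
#' \eqn{c > 0} and \eqn{d > 0}; otherwise no interior maximum exists and the
#' subject is flagged rather than assigned a boundary value.
#'
#' @param b,c,d Reed1 coefficients (kg/year, kg, kg-year). Vectorized.
#' @return Data frame with `t_pwv` (years), `pwv` (kg/year) and logical
#'   `valid`; invalid rows carry `NA`.
#' @export
pwv_from_coefficients <- function(b, c, d) {
  n <- max(length(b), length(c), length(d))
  b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  valid <- !is.na(c) & !is.na(d) & c > 0 & d > 0
  t_star <- ifelse(valid, 2 * d / c, NA_real_)
  pwv <- ifelse(valid, b + c^2 / (4 * d), NA_real_)
  data.frame(t_pwv = t_star, pwv = pwv, valid = valid)
}

#' Fit the Reed1 infant weight model
#'
#' Linear-in-parameters mixed model on the basis \{1, t, ln t, 1/t\}, fitted
#' per sex by REML (or a plain least-squares fit when `random = "none"`).
#' Per-subject coefficients are fixed effects plus predicted (BLUP) random
#' effects; PWV and its age come from the closed forms.
#'
#' @param data Data frame with columns `subject_id`, `sex`, `age_years`
#'   (> 0; map birth to `birth_offset` before calling or pass age 0 and it
#'   is mapped here), `weight_kg`.
#' @param random Character vector of coefficients carrying random effects,
#'   a subset of `c("a", "b", "c", "d")`, or `"none"`. Default intercept +
#'   linear slope, so peak weight velocity varies between subjects.
#' @param birth_offset Age assigned to birth-weight rows with age 0, years.
#' @param min_obs Minimum weight measurements per subject; subjects below it
#'   are dropped (counted in the result).
#' @return A `reed1_fit` with per-sex fixed effects, residual SD, and a
#'   per-subject table (`subject_id`, `sex`, `a`, `b`, `c`, `d`, `t_pwv`,
#'   `pwv`, `valid`).
#' @export
fit_reed1 <- function(data, random = c("a", "b"), birth_offset = 3 / 365.25,
                      min_obs = 4) {
  need <- c("subject_id", "sex", "age_years", "weight_kg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ec("schema_error", "missing column(s): %s", paste(miss, collapse = ", "))
  }
  d <- data[!is.na(data$age_years) & !is.na(data$weight_kg), , drop = FALSE]
  d$age_years[d$age_years == 0] <- birth_offset
  if (any(d$age_years <= 0) || any(d$age_years > 3)) {
    stop_ec("validation_error", "ages must lie in (0, 3] years")
  }
  cnt <- table(d$subject_id)
  keep <- names(cnt)[cnt >= min_obs]
  n_dropped <- length(cnt) - length(keep)
  d <- d[d$subject_id %in% keep, , drop = FALSE]
  if (!nrow(d)) stop_ec("insufficient_data", "no subjects with >= %d measurements", min_obs)

  re_map <- c(a = "1", b = "t", c = "lnt", d = "invt")
  if (!identical(random, "none")) {
    bad <- setdiff(random, names(re_map))
    if (length(bad)) {
      stop_ec("configuration_error", "unknown random-effect term(s): %s",
              paste(bad, collapse = ", "))
    }
  }

  fits <- lapply(split(d, as.character(d$sex)), function(ds) {
    B <- reed1_basis(ds$age_years)
    df <- data.frame(w = ds$weight_kg, t = B[, "t"], lnt = B[, "lnt"],
                     invt = B[, "invt"], subject_id = ds$subject_id)
    if (identical(random, "none")) {
      fit <- stats::lm(w ~ t + lnt + invt, data = df)
      fe <- stats::coef(fit)
      subj <- unique(ds$subject_id)
      co <- data.frame(subject_id = subj,
                       a = fe[["(Intercept)"]], b = fe[["t"]],
                       c = fe[["lnt"]], d = fe[["invt"]])
      list(fixef = fe, sigma = stats::sigma(fit), coef = co,
           converged = TRUE, messages = character(0))
    } else {
      re_terms <- paste(ifelse(random == "a", "1", re_map[random]),
                        collapse = " + ")
      re_part <- if ("a" %in% random) re_terms else paste0("0 + ", re_terms)
      form <- stats::as.formula(
        sprintf("w ~ t + lnt + invt + (%s | subject_id)", re_part))
      fit <- lme4::lmer(form, data = df, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
      fe <- lme4::fixef(fit)
      re <- lme4::ranef(fit)$subject_id
      co <- data.frame(subject_id = rownames(re),
                       a = fe[["(Intercept)"]], b = fe[["t"]],
                       c = fe[["lnt"]], d = fe[["invt"]])
      add <- c(a = "(Intercept)", b = "t", c = "lnt", d = "invt")
      for (p in names(add)) {
        if (add[[p]] %in% colnames(re)) co[[p]] <- co[[p]] + re[[add[[p]]]]
      }
      msgs <- unlist(fit@optinfo$conv$lme4$messages) %||% character(0)
      list(fixef = fe, sigma = stats::sigma(fit), coef = co,
           converged = length(msgs) == 0, messages = msgs)
    }
  })

  coef_tab <- do.call(rbind, lapply(names(fits), function(s) {
    co <- fits[[s]]$coef
    co$sex <- s
    co
  }))
  pk <- pwv_from_coefficients(coef_tab$b, coef_tab$c, coef_tab$d)
  # an interior maximum must also lie inside the observed window (0, 3]
  pk$valid <- pk$valid & !is.na(pk$t_pwv) & pk$t_pwv <= 3
  pk$t_pwv[!pk$valid] <- NA_real_
  pk$pwv[!pk$valid] <- NA_real_
  subjects <- cbind(coef_tab[, c("subject_id", "sex", "a", "b", "c", "d")], pk)
  rownames(subjects) <- NULL

  structure(list(
    by_sex = lapply(fits, function(f) f[c("fixef", "sigma", "converged", "messages")]),
    subjects = subjects,
    random = random,
    birth_offset = birth_offset,
    n_subjects = nrow(subjects),
    n_dropped_few_obs = n_dropped,
    n_flagged_no_peak = sum(!pk$valid)
  ), class = "reed1_fit")
}

#' @export
print.reed1_fit <- function(x, ...) {
  cat(sprintf("<reed1_fit> %d subjects (%d dropped for few obs, %d without interior velocity peak)\n",
              x$n_subjects, x$n_dropped_few_obs, x$n_flagged_no_peak))
  for (s in names(x$by_sex)) {
    fe <- x$by_sex[[s]]$fixef
    cat(sprintf("  %s: a=%.3f b=%.3f c=%.3f d=%.4f sigma=%.3f%s\n", s,
                fe[["(Intercept)"]], fe[["t"]], fe[["lnt"]], fe[["invt"]],
                x$by_sex[[s]]$sigma,
                if (x$by_sex[[s]]$converged) "" else " [convergence messages]"))
  }
  invisible(x)
}

#' Stationary maximum of a subject-level BMI cubic
#'
#' For \eqn{f(t) = \beta_1 t + \beta_2 t^2 + \beta_3 t^3} (plus any
#' intercept), the stationary points solve
#' \eqn{\beta_1 + 2\beta_2 t + 3\beta_3 t^2 = 0}; the admissible peak is the
#' in-window root with \eqn{2\beta_2 + 6\beta_3 t < 0}. When
#' \eqn{|\beta_3| < 10^{-10}} the curve is a quadratic and the vertex
#' \eqn{-\beta_1/(2\beta_2)} is used (requiring \eqn{\beta_2 < 0}).
#'
#' @param b1,b2,b3 Subject-level cubic coefficients. Vectorized.
#' @param window Admissible age window in years.
#' @return Data frame with `t_peak` (years) and logical `valid`.
#' @export
adiposity_peak <- function(b1, b2, b3, window = c(14 / 365.25, 1.5)) {
  n <- max(length(b1), length(b2), length(b3))
  b1 <- rep_len(b1, n); b2 <- rep_len(b2, n); b3 <- rep_len(b3, n)
  t_peak <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (anyNA(c(b1[i], b2[i], b3[i]))) next
    if (abs(b3[i]) < 1e-10) {
      if (b2[i] < 0) {
        cand <- -b1[i] / (2 * b2[i])
        if (cand >= window[1] && cand <= window[2]) t_peak[i] <- cand
      }
      next
    }
    disc <- b2[i]^2 - 3 * b1[i] * b3[i]
    if (disc < 0) next
    roots <- (-b2[i] + c(-1, 1) * sqrt(disc)) / (3 * b3[i])
    sec <- 2 * b2[i] + 6 * b3[i] * roots
    ok <- roots >= window[1] & roots <= window[2] & sec < 0
    if (any(ok)) t_peak[i] <- roots[ok][1]
  }
  data.frame(t_peak = t_peak, valid = !is.na(t_peak))
}

#' Fit the cubic log-BMI adiposity-peak model
#'
#' Mixed model \eqn{\log BMI = \beta_0 + \beta_1 t + \beta_2 t^2 +
#' \beta_3 t^3 + \gamma\,male + b_{0i} + b_{1i} t + \epsilon} over the
#' window 14 days to 1.5 years, with subject random intercept and linear
#' slope (configurable to intercept-only). Each subject's age and BMI at
#' adiposity peak come from the stationary-point formula applied to the
#' subject-level coefficients.
#'
#' @param data Data frame with columns `subject_id`, `sex`, `age_years`,
#'   `bmi` (> 0).
#' @param window Age window in years; observations outside it are dropped.
#' @param random `c("intercept", "linear")` (default) or `"intercept"`.
#' @param min_obs Minimum BMI measurements per subject inside the window.
#' @return An `adiposity_fit` with fixed effects, residual SD, and a
#'   per-subject table (`subject_id`, `sex`, `age_at_peak` in months,
#'   `bmi_at_peak` in kg/m^2, `valid`).
#' @export
fit_adiposity_curve <- function(data, window = c(14 / 365.25, 1.5),
                                random = c("intercept", "linear"),
                                min_obs = 3) {
  need <- c("subject_id", "sex", "age_years", "bmi")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ec("schema_error", "missing column(s): %s", paste(miss, collapse = ", "))
  }
  d <- data[!is.na(data$age_years) & !is.na(data$bmi), , drop = FALSE]
  if (any(d$bmi <= 0)) stop_ec("invalid_measurement", "BMI must be positive")
  d <- d[d$age_years >= window[1] & d$age_years <= window[2], , drop = FALSE]
  cnt <- table(d$subject_id)
  keep <- names(cnt)[cnt >= min_obs]
  n_dropped <- length(cnt) - length(keep)
  d <- d[d$subject_id %in% keep, , drop = FALSE]
  if (!nrow(d)) stop_ec("insufficient_data", "no subjects with >= %d in-window BMI measurements", min_obs)

  sex_chr <- as.character(d$sex)
  sex_lv <- sort(unique(sex_chr))
  df <- data.frame(y = log(d$bmi), t = d$age_years,
                   t2 = d$age_years^2, t3 = d$age_years^3,
                   sex = factor(sex_chr, levels = sex_lv),
                   subject_id = d$subject_id)
  re_part <- if (identical(random, "intercept")) "(1 | subject_id)" else "(1 + t | subject_id)"
  has_sex <- length(sex_lv) > 1
  fix_part <- if (has_sex) "y ~ t + t2 + t3 + sex" else "y ~ t + t2 + t3"
  fit <- lme4::lmer(stats::as.formula(paste(fix_part, "+", re_part)),
                    data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$subject_id
  subj_sex <- tapply(sex_chr, d$subject_id, function(v) v[1])
  subj <- rownames(re)
  b0 <- fe[["(Intercept)"]] + re[["(Intercept)"]]
  if (has_sex) {
    sex_term <- paste0("sex", sex_lv[2])
    b0 <- b0 + ifelse(subj_sex[subj] == sex_lv[2], fe[[sex_term]], 0)
  }
  b1 <- rep(fe[["t"]], length(subj))
  if ("t" %in% colnames(re)) b1 <- b1 + re[["t"]]
  b2 <- fe[["t2"]]; b3 <- fe[["t3"]]

  pk <- adiposity_peak(b1, b2, b3, window = window)
  bmi_at_peak <- ifelse(pk$valid,
                        exp(b0 + b1 * pk$t_peak + b2 * pk$t_peak^2 + b3 * pk$t_peak^3),
                        NA_real_)
  subjects <- data.frame(subject_id = subj, sex = unname(subj_sex[subj]),
                         b0 = b0, b1 = b1, b2 = b2, b3 = b3,
                         age_at_peak = pk$t_peak * 12,
                         bmi_at_peak = bmi_at_peak, valid = pk$valid)
  rownames(subjects) <- NULL
  if (!any(pk$valid)) {
    warning("no subject has an interior adiposity peak inside the window")
  }
  msgs <- unlist(fit@optinfo$conv$lme4$messages) %||% character(0)
  structure(list(fixef = fe, sigma = stats::sigma(fit), subjects = subjects,
                 window = window, random = random,
                 converged = length(msgs) == 0, messages = msgs,
                 n_subjects = nrow(subjects), n_dropped_few_obs = n_dropped,
                 n_flagged_no_peak = sum(!pk$valid)),
            class = "adiposity_fit")
}

#' @export
print.adiposity_fit <- function(x, ...) {
  cat(sprintf("<adiposity_fit> %d subjects (%d dropped for few obs, %d without interior peak)\n",
              x$n_subjects, x$n_dropped_few_obs, x$n_flagged_no_peak))
  cat("  fixed effects:", paste(sprintf("%s=%.4f", names(x$fixef), x$fixef),
                                collapse = ", "), "\n")
  invisible(x)
}
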