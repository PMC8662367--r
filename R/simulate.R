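# Synthetic-cohort generator.
#
# Emulates the measurement schedule and marginal structure of a large
# pregnancy cohort with fetal ultrasound at the second and third trimester,
# birth records, infant visits around 6, 12 and 24 months, an infant BMI
# series, and a childhood neuroimaging visit. The statistical skeleton:
#
#   * one latent growth z per weight occasion, following a first-order
#     autoregressive chain (lag-1 tracking correlation, default 0.7), shifted
#     by confounder effects;
#   * fetal/birth weights lognormal around a gestational-age median curve;
#   * infant weights = sex-specific Reed1 curve + an occasion-scaled z
#     offset + measurement noise, so trajectory fitting has a true model;
#   * BMI series from the generating cubic on log BMI with subject random
#     intercept and slope;
#   * brain outcomes linear in the configured exposures and confounders plus
#     Gaussian noise;
#   * missingness MCAR per variable, except 24-month weight, which is
#     missing-at-random given household income to exercise the endpoint
#     fallback rule non-trivially.
#
# Ground truth (latent z, subject-level curve coefficients, true effects) is
# emitted alongside the data so recovery tests never re-derive it.

#' Default simulation configuration
#'
#' All knobs of the synthetic cohort. Defaults are calibrated once to the
#' marginal summaries of a large population-based pregnancy cohort (median
#' estimated fetal weights of 362 g and 1602 g at 20.5 and 30.4 weeks, mean
#' birth weight 3446 g, infant weight medians 7.8/9.6/12.8 kg, adiposity
#' peak near 8.4 months at BMI 17.6, covariate frequencies such as 50.3%
#' girls and 20.4% maternal smoking). Tests compare against the config
#' values, which are the generating truth.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; fully determines the output.
#' @param tracking Lag-1 correlation of the latent growth z chain.
#' @param ... Replacements for any top-level config element.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 3000, seed = 1L, tracking = 0.7, ...) {
  cfg <- list(
    n = n, seed = seed, tracking = tracking,
    schedule = list(
      t2_ga = c(mean = 20.5, sd = 1.17), t3_ga = c(mean = 30.4, sd = 1.07),
      birth_ga = c(max = 42.8, shape = 3, scale = 0.95),
      m6 = c(median = 6.2, logsd = 0.124), m12 = c(median = 11.0, logsd = 0.085),
      m24 = c(median = 24.8, logsd = 0.064),
      age_mri = c(mean = 10.1, sd = 0.6)),
    fetal = list(
      median_anchors = cbind(ga = c(20.5, 30.4, 40.1),
                             w = c(362, 1602, 3450)),
      logsd_anchors = cbind(ga = c(20.5, 30.4, 40.1),
                            s = c(0.2303, 0.1518, 0.1595)),
      birth_weight_mean = 3446),
    biometry = list(ga = c(20.5, 30.4),
                    hc = c(20.0, 28.5), ac = c(16.0, 26.5), fl = c(3.0, 5.8)),
    reed1 = list(
      female = c(a = 8.145, b = 1.482, c = 1.7701, d = 0.03009),
      male = c(a = 8.395, b = 1.582, c = 1.7701, d = 0.03009),
      gamma = c(m6 = 0.85, m12 = 1.00, m24 = 1.45),
      resid_sd = 0.10),
    bmi = list(
      beta = c(b0 = 2.528, b1 = 1.070, b2 = -0.979, b3 = 0.204),
      sex_effect = 0.012, sd_b0 = 0.045, sd_b1 = 0.042, resid_sd = 0.025,
      visits_months = c(0.5, 3, 6.2, 11, 14), visit_jitter_logsd = 0.06,
      window = c(14 / 365.25, 1.5)),
    covariates = list(
      p_female = 0.503,
      m_age = c(mean = 31.1, sd = 4.9),
      ethnicity = c(dutch = 0.578, other_nonwestern = 0.339, other_western = 0.083),
      m_bmi = c(median = 22.5, logsd = 0.168),
      education = c(primary = 0.065, secondary = 0.406, higher = 0.529),
      income = c(low = 0.137, mid = 0.158, high = 0.705),
      folic = 0.799, alcohol = 0.506, smoking = 0.204,
      child_bmi_cor = 0.4),
    confounder_effects = list(
      exposure = c(smoking = -0.30, m_bmi_z = 0.15, education_higher = 0.10),
      outcome = list(
        total_brain_volume = c(smoking = -8, m_bmi_z = -3, education_higher = 5),
        cerebral_gray_volume = c(smoking = -4, m_bmi_z = -1.5, education_higher = 2.5),
        head_circumference_10y = c(smoking = -0.15, m_bmi_z = -0.05,
                                   education_higher = 0.08))),
    effects = list(
      total_brain_volume = c(z_birth = 20, ga_birth = 4.7),
      cerebral_gray_volume = c(z_birth = 9.8, ga_birth = 2.6),
      head_circumference_10y = c(z_birth = 0.35, ga_birth = 0.1)),
    outcomes = list(
      total_brain_volume = c(base = 1130, sex_male = 75, age_slope = 3, sd = 55),
      cerebral_gray_volume = c(base = 600, sex_male = 40, age_slope = 1, sd = 30),
      head_circumference_10y = c(base = 52.6, sex_male = 0.8, age_slope = 0.2, sd = 1.3)),
    icv = c(offset = 140, sd = 20),
    missingness = list(
      mcar = c(t2 = 0.03, t3 = 0.03, m6 = 0.08, m12 = 0.10,
               ethnicity = 0.021, education = 0.081, income = 0.222,
               folic = 0.299, alcohol = 0.209, smoking = 0.209, m_bmi = 0.05,
               bmi_visit = 0.07),
      m24_mar = c(base = 0.25, income_low_extra = 0.25))
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop_ec("configuration_error", "unknown config element(s): %s",
            paste(bad, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  rates <- c(cfg$missingness$mcar, cfg$missingness$m24_mar)
  if (any(rates < 0 | rates > 1)) {
    stop_ec("configuration_error", "missingness rates must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# quadratic in ga through the three log-median anchors
fetal_log_median <- function(cfg_fetal) {
  A <- cbind(1, cfg_fetal$median_anchors[, "ga"], cfg_fetal$median_anchors[, "ga"]^2)
  co <- solve(A, log(cfg_fetal$median_anchors[, "w"]))
  function(ga) co[1] + co[2] * ga + co[3] * ga^2
}

fetal_logsd <- function(cfg_fetal) {
  an <- cfg_fetal$logsd_anchors
  function(ga) stats::approx(an[, "ga"], an[, "s"], xout = ga, rule = 2)$y
}

reed1_curve <- function(coefs, t) {
  coefs[["a"]] + coefs[["b"]] * t + coefs[["c"]] * log(t) + coefs[["d"]] / t
}

# scale factor f such that the Hadlock EFW of (f*hc, f*ac, f*fl) equals w
biometry_scale <- function(w, hc0, ac0, fl0, k = hadlock_coefficients()) {
  A <- k$c1 * ac0 * fl0
  B <- k$c2 * hc0 + k$c3 * ac0 + k$c4 * fl0
  C <- k$c0 - log10(w)
  disc <- B^2 - 4 * A * C
  (-B + sqrt(pmax(disc, 0))) / (2 * A)
}

#' Simulate a synthetic cohort
#'
#' @param config A [sim_config()] list.
#' @return Object of class `synthetic_cohort`: a list with
#'   * `long` -- one row per subject-by-occasion measurement (fetal occasions
#'     in grams and gestational weeks with HC/AC/FL biometry, infant
#'     occasions in kilograms and months); missing visits are absent rows;
#'   * `bmi` -- the infant BMI series (`subject_id`, `sex`, `age_years`, `bmi`);
#'   * `wide` -- per-subject covariates, outcomes and birth facts;
#'   * `truth` -- ground truth: latent z per occasion, subject-level Reed1 and
#'     BMI-curve coefficients with their closed-form peaks, and the
#'     configured effects.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  occ <- c("t2", "t3", "birth", "m6", "m12", "m24")
  if (n == 0) {
    long <- data.frame(subject_id = character(0), sex = character(0),
                       occasion = character(0), age = numeric(0),
                       weight = numeric(0), hc = numeric(0), ac = numeric(0),
                       fl = numeric(0))
    bmi <- data.frame(subject_id = character(0), sex = character(0),
                      age_years = numeric(0), bmi = numeric(0))
    wide <- data.frame(subject_id = character(0))
    truth <- list(z = matrix(numeric(0), 0, 6, dimnames = list(NULL, occ)),
                  effects = config$effects)
    return(structure(list(long = long, bmi = bmi, wide = wide, truth = truth,
                          config = config), class = "synthetic_cohort"))
  }
  set.seed(config$seed)
  id <- sprintf("s%05d", seq_len(n))
  cv <- config$covariates
  sex <- ifelse(stats::runif(n) < cv$p_female, "female", "male")
  male <- as.numeric(sex == "male")
  m_age <- stats::rnorm(n, cv$m_age[["mean"]], cv$m_age[["sd"]])
  ethnicity <- sample(names(cv$ethnicity), n, TRUE, prob = cv$ethnicity)
  m_bmi <- exp(log(cv$m_bmi[["median"]]) + cv$m_bmi[["logsd"]] * stats::rnorm(n))
  m_bmi_z <- (log(m_bmi) - log(cv$m_bmi[["median"]])) / cv$m_bmi[["logsd"]]
  education <- sample(names(cv$education), n, TRUE, prob = cv$education)
  income <- sample(names(cv$income), n, TRUE, prob = cv$income)
  folic <- ifelse(stats::runif(n) < cv$folic, "yes", "no")
  alcohol <- ifelse(stats::runif(n) < cv$alcohol, "yes", "no")
  smoking <- ifelse(stats::runif(n) < cv$smoking, "yes", "no")

  ce <- config$confounder_effects$exposure
  mu_shift <- ce[["smoking"]] * (smoking == "yes") +
    ce[["m_bmi_z"]] * m_bmi_z +
    ce[["education_higher"]] * (education == "higher")

  rho <- config$tracking
  z <- matrix(NA_real_, n, 6, dimnames = list(NULL, occ))
  z[, 1] <- stats::rnorm(n)
  innov_sd <- sqrt(max(0, 1 - rho^2))
  for (k in 2:6) z[, k] <- rho * z[, k - 1] + innov_sd * stats::rnorm(n)
  z <- z + mu_shift # confounder shift enters every occasion

  sc <- config$schedule
  ga_t2 <- pmin(pmax(stats::rnorm(n, sc$t2_ga[["mean"]], sc$t2_ga[["sd"]]), 17.5), 24)
  ga_t3 <- pmin(pmax(stats::rnorm(n, sc$t3_ga[["mean"]], sc$t3_ga[["sd"]]), 27), 34)
  ga_birth <- sc$birth_ga[["max"]] -
    stats::rgamma(n, shape = sc$birth_ga[["shape"]], scale = sc$birth_ga[["scale"]])
  ga_birth <- pmin(pmax(ga_birth, ga_t3 + 1.5), 44.5)
  age_m6 <- exp(log(sc$m6[["median"]]) + sc$m6[["logsd"]] * stats::rnorm(n))
  age_m12 <- exp(log(sc$m12[["median"]]) + sc$m12[["logsd"]] * stats::rnorm(n))
  age_m24 <- exp(log(sc$m24[["median"]]) + sc$m24[["logsd"]] * stats::rnorm(n))
  age_mri <- stats::rnorm(n, sc$age_mri[["mean"]], sc$age_mri[["sd"]])

  logmu <- fetal_log_median(config$fetal)
  logsd <- fetal_logsd(config$fetal)
  w_t2 <- exp(logmu(ga_t2) + logsd(ga_t2) * z[, "t2"])
  w_t3 <- exp(logmu(ga_t3) + logsd(ga_t3) * z[, "t3"])
  w_birth <- exp(logmu(ga_birth) + logsd(ga_birth) * z[, "birth"])

  bio <- config$biometry
  bio_at <- function(dim, ga) {
    b <- bio[[dim]]
    b[1] + (b[2] - b[1]) * (ga - bio$ga[1]) / (bio$ga[2] - bio$ga[1])
  }
  biom_for <- function(ga, w) {
    hc0 <- bio_at("hc", ga); ac0 <- bio_at("ac", ga); fl0 <- bio_at("fl", ga)
    f <- biometry_scale(w, hc0, ac0, fl0)
    list(hc = f * hc0, ac = f * ac0, fl = f * fl0)
  }
  biom <- list(t2 = biom_for(ga_t2, w_t2), t3 = biom_for(ga_t3, w_t3))

  r1 <- config$reed1
  curves <- rbind(female = r1$female, male = r1$male)
  t_inf <- cbind(m6 = age_m6, m12 = age_m12, m24 = age_m24) / 12
  gamma <- r1$gamma
  w_inf <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("m6", "m12", "m24")))
  for (v in colnames(w_inf)) {
    tv <- t_inf[, v]
    a <- curves[sex, "a"]; b <- curves[sex, "b"]
    cc <- curves[sex, "c"]; dd <- curves[sex, "d"]
    w_inf[, v] <- a + b * tv + cc * log(tv) + dd / tv +
      gamma[[v]] * z[, v] + stats::rnorm(n, 0, r1$resid_sd)
  }

  # subject-level true Reed1 coefficients: sex curve plus the least-squares
  # projection of the deterministic z offsets onto {1, t}
  off <- sweep(z[, c("m6", "m12", "m24")], 2, gamma[c("m6", "m12", "m24")], `*`)
  tbar <- rowMeans(t_inf)
  obar <- rowMeans(off)
  slope <- rowSums((t_inf - tbar) * (off - obar)) / rowSums((t_inf - tbar)^2)
  icept <- obar - slope * tbar
  true_a <- curves[sex, "a"] + icept
  true_b <- curves[sex, "b"] + slope
  true_pk <- pwv_from_coefficients(true_b, curves[sex, "c"], curves[sex, "d"])

  bc <- config$bmi
  b0_i <- stats::rnorm(n, 0, bc$sd_b0)
  b1_i <- stats::rnorm(n, 0, bc$sd_b1)
  nv <- length(bc$visits_months)
  bmi_rows <- vector("list", nv)
  for (j in seq_len(nv)) {
    am <- bc$visits_months[j] *
      exp(stats::rnorm(n, 0, bc$visit_jitter_logsd))
    am <- pmax(am, 14 / 365.25 * 12 + 0.02)
    ty <- am / 12
    lb <- bc$beta[["b0"]] + bc$sex_effect * male + b0_i +
      (bc$beta[["b1"]] + b1_i) * ty + bc$beta[["b2"]] * ty^2 +
      bc$beta[["b3"]] * ty^3 + stats::rnorm(n, 0, bc$resid_sd)
    bmi_rows[[j]] <- data.frame(subject_id = id, sex = sex, age_years = ty,
                                bmi = exp(lb))
  }
  bmi_long <- do.call(rbind, bmi_rows)
  true_bmi_peak <- adiposity_peak(bc$beta[["b1"]] + b1_i, bc$beta[["b2"]],
                                  bc$beta[["b3"]], window = bc$window)
  true_bmi_at_peak <- ifelse(
    true_bmi_peak$valid,
    exp(bc$beta[["b0"]] + bc$sex_effect * male + b0_i +
          (bc$beta[["b1"]] + b1_i) * true_bmi_peak$t_peak +
          bc$beta[["b2"]] * true_bmi_peak$t_peak^2 +
          bc$beta[["b3"]] * true_bmi_peak$t_peak^3),
    NA_real_)

  child_bmi_z <- cv$child_bmi_cor * z[, "m24"] +
    sqrt(1 - cv$child_bmi_cor^2) * stats::rnorm(n)

  co <- config$confounder_effects$outcome
  outs <- list()
  for (oc in names(config$outcomes)) {
    pr <- config$outcomes[[oc]]
    eff <- config$effects[[oc]] %||% numeric(0)
    y <- pr[["base"]] + pr[["sex_male"]] * male +
      pr[["age_slope"]] * (age_mri - sc$age_mri[["mean"]])
    if ("z_birth" %in% names(eff)) y <- y + eff[["z_birth"]] * z[, "birth"]
    if ("ga_birth" %in% names(eff)) y <- y + eff[["ga_birth"]] * (ga_birth - 40)
    ce_o <- co[[oc]] %||% numeric(0)
    if ("smoking" %in% names(ce_o)) y <- y + ce_o[["smoking"]] * (smoking == "yes")
    if ("m_bmi_z" %in% names(ce_o)) y <- y + ce_o[["m_bmi_z"]] * m_bmi_z
    if ("education_higher" %in% names(ce_o)) {
      y <- y + ce_o[["education_higher"]] * (education == "higher")
    }
    outs[[oc]] <- y + stats::rnorm(n, 0, pr[["sd"]])
  }
  icv <- outs[["total_brain_volume"]] + config$icv[["offset"]] +
    stats::rnorm(n, 0, config$icv[["sd"]])

  # -- missingness ---------------------------------------------------------
  mcar <- config$missingness$mcar
  miss <- list(
    t2 = stats::runif(n) < mcar[["t2"]],
    t3 = stats::runif(n) < mcar[["t3"]],
    m6 = stats::runif(n) < mcar[["m6"]],
    m12 = stats::runif(n) < mcar[["m12"]]
  )
  p24 <- config$missingness$m24_mar[["base"]] +
    config$missingness$m24_mar[["income_low_extra"]] * (income == "low")
  miss$m24 <- stats::runif(n) < p24
  for (v in c("ethnicity", "education", "income", "folic", "alcohol",
              "smoking", "m_bmi")) {
    sel <- stats::runif(n) < mcar[[v]]
    val <- get(v, inherits = FALSE)
    val[sel] <- NA
    assign(v, val, inherits = FALSE)
  }
  bmi_keep <- stats::runif(nrow(bmi_long)) >= mcar[["bmi_visit"]]
  bmi_long <- bmi_long[bmi_keep, , drop = FALSE]

  mk_row <- function(occ_lab, age, weight, hc = NA_real_, ac = NA_real_,
                     fl = NA_real_, keep = rep(TRUE, n)) {
    data.frame(subject_id = id, sex = sex, occasion = occ_lab, age = age,
               weight = weight, hc = hc, ac = ac, fl = fl)[keep, , drop = FALSE]
  }
  long <- rbind(
    mk_row("T2", ga_t2, w_t2, biom$t2$hc, biom$t2$ac, biom$t2$fl, !miss$t2),
    mk_row("T3", ga_t3, w_t3, biom$t3$hc, biom$t3$ac, biom$t3$fl, !miss$t3),
    mk_row("birth", ga_birth, w_birth),
    mk_row("m6", age_m6, w_inf[, "m6"], keep = !miss$m6),
    mk_row("m12", age_m12, w_inf[, "m12"], keep = !miss$m12),
    mk_row("m24", age_m24, w_inf[, "m24"], keep = !miss$m24)
  )
  rownames(long) <- NULL

  wide <- data.frame(
    subject_id = id, sex = sex, age_mri = age_mri,
    m_age = m_age, ethnicity = ethnicity, m_bmi = m_bmi,
    education = education, income = income, smoking = smoking,
    alcohol = alcohol, folic = folic, child_bmi_z = child_bmi_z,
    ga_birth = ga_birth, birth_weight_g = w_birth, icv = icv)
  for (oc in names(outs)) wide[[oc]] <- outs[[oc]]

  truth <- list(
    z = z, mu_shift = mu_shift,
    effects = config$effects,
    confounder_effects = config$confounder_effects,
    reed1 = list(curves = curves,
                 subjects = data.frame(subject_id = id, sex = sex,
                                       a = unname(true_a), b = unname(true_b),
                                       c = unname(curves[sex, "c"]),
                                       d = unname(curves[sex, "d"]),
                                       t_pwv = true_pk$t_pwv,
                                       pwv = true_pk$pwv)),
    bmi = list(beta = bc$beta, sex_effect = bc$sex_effect,
               subjects = data.frame(subject_id = id,
                                     b0 = b0_i, b1 = b1_i,
                                     age_at_peak = true_bmi_peak$t_peak * 12,
                                     bmi_at_peak = true_bmi_at_peak,
                                     valid = true_bmi_peak$valid)),
    missing = list(m24_rate = mean(miss$m24), m12_rate = mean(miss$m12),
                   m6_rate = mean(miss$m6))
  )
  structure(list(long = long, bmi = bmi_long, wide = wide, truth = truth,
                 config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n=%d subjects, %d measurement rows, %d BMI rows (seed %s)\n",
              nrow(x$wide), nrow(x$long), nrow(x$bmi),
              format(x$config$seed)))
  invisible(x)
}

#' Ground-truth summary of a synthetic cohort
#'
#' Reports the configured effects, the true growth-pattern category counts
#' implied by the latent z chain, and summaries of true per-subject peak
#' weight velocity and adiposity peak, all computed from the generating
#' coefficients via the closed forms.
#'
#' @param cohort A `synthetic_cohort`.
#' @param threshold Change threshold for the category counts.
#' @return A list.
#' @export
truth_report <- function(cohort, threshold = 0.67) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  z <- cohort$truth$z
  if (!nrow(z)) {
    return(list(n = 0, effects = cohort$truth$effects))
  }
  fc <- classify_delta(z[, "birth"] - z[, "t2"], threshold)
  ic <- classify_delta(z[, "m24"] - z[, "birth"], threshold)
  pat <- combine_patterns(fc, ic)
  list(
    n = nrow(z),
    effects = cohort$truth$effects,
    fetal_change = table(fc),
    infant_change = table(ic),
    pattern9 = table(pat$pattern9),
    pwv = summary(cohort$truth$reed1$subjects$pwv),
    age_at_peak_months = summary(cohort$truth$bmi$subjects$age_at_peak),
    bmi_at_peak = summary(cohort$truth$bmi$subjects$bmi_at_peak)
  )
}
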