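# Pipeline orchestration: standardize -> classify -> conditional ->
# trajectories -> (impute) -> associate -> report. Each stage logs the
# number of subjects entering and leaving (with exclusion reasons) so the
# differing per-analysis n's are accounted for, and a manifest records the
# seed and a hash of the configuration.

#' Build a wide SD-score table from a long cohort table
#'
#' Fits the internal references (fetal weight on the log scale without sex
#' stratification; birth and infant weight on the raw scale per sex) and
#' evaluates the per-occasion SD scores.
#'
#' @param long Long measurement table (see [validate_growth_long()]).
#' @param n_knots Spline knots for the internal references.
#' @return List with `wide` (one row per subject: `z_t2`, `z_t3`, `z_birth`,
#'   `z_m6`, `z_m12`, `z_m24`, plus `ga_birth` and `birth_weight_g`) and
#'   `references` (the three fitted `growth_reference` objects).
#' @export
standardize_cohort <- function(long, n_knots = 4) {
  long <- validate_growth_long(long)
  fet <- long[long$occasion %in% c("T2", "T3"), , drop = FALSE]
  bir <- long[long$occasion == "birth", , drop = FALSE]
  inf <- long[long$occasion %in% c("m6", "m12", "m24"), , drop = FALSE]

  ref_fetal <- fit_internal_reference(fet, by_sex = FALSE, log_scale = TRUE,
                                      n_knots = n_knots)
  ref_birth <- fit_internal_reference(bir, by_sex = TRUE, log_scale = FALSE,
                                      n_knots = n_knots)
  ref_infant <- fit_internal_reference(inf, by_sex = TRUE, log_scale = FALSE,
                                       n_knots = n_knots)

  ids <- unique(long$subject_id)
  wide <- data.frame(subject_id = ids)
  sex_of <- tapply(as.character(long$sex), long$subject_id, `[`, 1)
  wide$sex <- unname(sex_of[as.character(ids)])

  put <- function(wide, rows, ref, col, use_sex) {
    zz <- sd_score(rows$weight, rows$age, ref,
                   sex = if (use_sex) rows$sex else NULL)
    wide[[col]] <- zz[match(wide$subject_id, rows$subject_id)]
    wide
  }
  wide <- put(wide, long[long$occasion == "T2", ], ref_fetal, "z_t2", FALSE)
  wide <- put(wide, long[long$occasion == "T3", ], ref_fetal, "z_t3", FALSE)
  wide <- put(wide, bir, ref_birth, "z_birth", TRUE)
  wide <- put(wide, long[long$occasion == "m6", ], ref_infant, "z_m6", TRUE)
  wide <- put(wide, long[long$occasion == "m12", ], ref_infant, "z_m12", TRUE)
  wide <- put(wide, long[long$occasion == "m24", ], ref_infant, "z_m24", TRUE)
  wide$ga_birth <- bir$age[match(wide$subject_id, bir$subject_id)]
  wide$birth_weight_g <- bir$weight[match(wide$subject_id, bir$subject_id)]
  list(wide = wide,
       references = list(fetal = ref_fetal, birth = ref_birth,
                         infant = ref_infant))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in dependency order and emits the four report tables:
#' birth outcomes, critical periods (conditional growth), the nine
#' fetal-by-infant growth patterns, and the infant growth parameters (peak
#' weight velocity, BMI and age at adiposity peak).
#'
#' @param cohort A `synthetic_cohort`, or any list with elements `long`,
#'   `bmi` and `wide` following the same contracts.
#' @param tier Model tier for the report tables.
#' @param outcomes Outcome columns to analyze.
#' @param impute Multiply impute missing covariates and pool estimates?
#' @param m Number of imputations when `impute = TRUE`.
#' @param analyses Subset of the four analyses to run.
#' @param threshold Growth-change threshold in SD-score units.
#' @param seed Seed for the imputation stage (defaults to the cohort seed).
#' @return List of class `growth_pipeline_result` with `features` (wide
#'   per-subject table with all derived exposures), `references`,
#'   `conditional`, `reed1`, `adiposity`, `tables`, `log` (per-stage n
#'   accounting) and `manifest`.
#' @export
run_pipeline <- function(cohort, tier = "confounder",
                         outcomes = c("total_brain_volume",
                                      "cerebral_gray_volume",
                                      "head_circumference_10y"),
                         impute = FALSE, m = 30,
                         analyses = c("birth_outcomes", "critical_periods",
                                      "growth_patterns", "infant_growth"),
                         threshold = 0.67, seed = NULL) {
  known <- c("birth_outcomes", "critical_periods", "growth_patterns",
             "infant_growth")
  bad <- setdiff(analyses, known)
  if (length(bad)) {
    stop_ec("configuration_error", "unknown analysis recipe(s): %s",
            paste(bad, collapse = ", "))
  }
  log <- list()
  note <- function(stage, n_in, n_out, reason = NA_character_) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out, reason = reason)
  }

  # 1. standardize
  st <- standardize_cohort(cohort$long)
  wide <- st$wide
  note("standardize", length(unique(cohort$long$subject_id)), nrow(wide))

  # 2. classify
  wide <- growth_features(wide, threshold = threshold)
  counts <- attr(wide, "classification_counts")
  note("classify", nrow(wide), sum(!is.na(wide$pattern9)),
       "subjects with unresolved pattern carry NA")

  # 3. conditional growth
  cond <- fit_conditional_set(wide)
  cw <- apply_conditional_set(cond, wide)
  wide <- cbind(wide, cw)
  note("conditional", nrow(wide), cond$n_complete, "complete weight series only")

  # 4. trajectories
  inf_rows <- cohort$long[cohort$long$occasion %in% c("m6", "m12", "m24"), ]
  bir_rows <- cohort$long[cohort$long$occasion == "birth", ]
  traj_dat <- rbind(
    data.frame(subject_id = bir_rows$subject_id, sex = bir_rows$sex,
               age_years = 0, weight_kg = bir_rows$weight / 1000),
    data.frame(subject_id = inf_rows$subject_id, sex = inf_rows$sex,
               age_years = inf_rows$age / 12, weight_kg = inf_rows$weight))
  reed1 <- fit_reed1(traj_dat, min_obs = 3)
  idx <- match(wide$subject_id, reed1$subjects$subject_id)
  wide$pwv <- reed1$subjects$pwv[idx]
  wide$t_pwv <- reed1$subjects$t_pwv[idx]
  note("reed1", nrow(wide), sum(!is.na(wide$pwv)),
       "needs 3 weights in (0,3] y and an interior velocity peak")

  adip <- fit_adiposity_curve(cohort$bmi, min_obs = 3)
  idx <- match(wide$subject_id, adip$subjects$subject_id)
  wide$age_at_peak <- adip$subjects$age_at_peak[idx]
  wide$bmi_at_peak <- adip$subjects$bmi_at_peak[idx]
  note("adiposity", nrow(wide), sum(!is.na(wide$age_at_peak)),
       "needs 3 in-window BMI values and an interior peak")

  # 5. merge covariates/outcomes
  features <- merge(wide, cohort$wide[, setdiff(names(cohort$wide),
                                                c("sex", "ga_birth",
                                                  "birth_weight_g"))],
                    by = "subject_id", sort = TRUE)
  features$bw_500 <- features$birth_weight_g / 500

  covs <- tier_covariates(tier)
  # 6. imputation (covariates only; exposures/outcomes stay untouched)
  analysis_data <- features
  if (impute) {
    imp_cols <- c("subject_id", covs, outcomes)
    imp_vars <- covs[vapply(covs, function(v) anyNA(features[[v]]), logical(1))]
    run <- impute_covariates(features[, unique(imp_cols)], vars = imp_vars,
                             m = m, iterations = 5,
                             seed = seed %||% cohort$config$seed %||% 1L)
    analysis_data <- lapply(run$completed, function(d) {
      cbind(d, features[, setdiff(names(features), names(d)), drop = FALSE])
    })
    note("impute", nrow(features), nrow(features),
         sprintf("m=%d datasets; imputed: %s", m,
                 paste(imp_vars, collapse = ", ")))
  }

  # 7. association tables
  tables <- list()
  if ("birth_outcomes" %in% analyses) {
    tables$birth_outcomes <- run_table(
      analysis_data, outcomes,
      exposures = c("ga_birth", "ga_cat", "bw_500", "bw_cat", "z_birth",
                    "sga_cat"),
      covariates = covs,
      references = c(ga_cat = "term", bw_cat = "normal", sga_cat = "AGA"),
      tier = tier)
  }
  if ("critical_periods" %in% analyses) {
    tables$critical_periods <- run_table(
      analysis_data, outcomes,
      exposures = paste0("cond_", cond$occasions),
      covariates = covs, tier = tier)
  }
  if ("growth_patterns" %in% analyses) {
    tables$growth_patterns <- run_table(
      analysis_data, outcomes, exposures = "pattern9",
      covariates = covs,
      references = c(pattern9 = pattern9_levels()[1]), tier = tier)
  }
  if ("infant_growth" %in% analyses) {
    tables$infant_growth <- run_table(
      analysis_data, outcomes,
      exposures = c("pwv", "bmi_at_peak", "age_at_peak"),
      covariates = covs, tier = tier)
  }

  log_df <- do.call(rbind, log)
  manifest <- list(
    package_version = as.character(utils::packageVersion("earlygrowth")),
    seed = seed %||% cohort$config$seed %||% NA,
    tier = tier, impute = impute,
    config_hash = fnv1a32(paste(utils::capture.output(utils::str(cohort$config)),
                                collapse = "\n")))
  structure(list(features = features, references = st$references,
                 conditional = cond, reed1 = reed1, adiposity = adip,
                 classification_counts = counts, tables = tables,
                 log = log_df, manifest = manifest),
            class = "growth_pipeline_result")
}

#' @export
print.growth_pipeline_result <- function(x, ...) {
  cat(sprintf("<growth_pipeline_result> %d subjects, %d report table(s)\n",
              nrow(x$features), length(x$tables)))
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Compare participants with nonparticipants
#'
#' Descriptive loss-to-follow-up check: continuous variables by Welch t test
#' (or Mann-Whitney for skewed variables), categorical variables by Pearson
#' chi-squared, across a participation flag.
#'
#' @param data Data frame.
#' @param flag Name of a logical/binary participation column.
#' @param vars Variables to compare.
#' @param skewed Subset of `vars` compared with the Mann-Whitney test.
#' @return Data frame with one row per variable: test used and p-value.
#' @export
compare_participation <- function(data, flag, vars, skewed = character(0)) {
  g <- as.logical(data[[flag]])
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (v %in% skewed) {
        p <- stats::wilcox.test(x[g], x[!g])$p.value
        data.frame(variable = v, test = "mann-whitney", p = p)
      } else {
        p <- stats::t.test(x[g], x[!g])$p.value
        data.frame(variable = v, test = "t", p = p)
      }
    } else {
      p <- suppressWarnings(stats::chisq.test(table(x, g))$p.value)
      data.frame(variable = v, test = "chi-squared", p = p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
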