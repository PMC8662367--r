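# Birth-outcome categories and the 3x3 fetal-by-infant growth-pattern
# taxonomy. Threshold conventions: gestational-age term window is the closed
# interval [37, 42] weeks; normal birth weight is [2500, 4500] g; SGA/LGA are
# strictly below the 10th / above the 90th percentile of the birth-weight SD
# score; growth acceleration/deceleration require a change in SD score
# strictly greater than 0.67 in absolute value (exact +/-0.67 is normal).

#' Categorize birth outcomes
#'
#' @param gestational_age Gestational age at birth, weeks. Must lie in
#'   (20, 45).
#' @param birth_weight Birth weight, grams.
#' @param birthweight_z Sex- and gestational-age-adjusted birth-weight SD
#'   score.
#' @param empirical_percentiles If `TRUE`, SGA/LGA cutoffs are the empirical
#'   10th/90th percentiles of `birthweight_z`; the default uses the
#'   standard-normal percentiles \eqn{\Phi^{-1}(0.10)} and
#'   \eqn{\Phi^{-1}(0.90)}.
#' @return Data frame with factor columns `ga_cat` (preterm/term/postterm),
#'   `bw_cat` (low/normal/high) and `sga_cat` (SGA/AGA/LGA).
#' @export
classify_birth_outcomes <- function(gestational_age, birth_weight,
                                    birthweight_z,
                                    empirical_percentiles = FALSE) {
  ok <- !is.na(gestational_age)
  if (any(gestational_age[ok] <= 20 | gestational_age[ok] >= 45)) {
    stop_ec("validation_error",
            "gestational age at birth must lie in (20, 45) weeks")
  }
  if (any(birth_weight[!is.na(birth_weight)] <= 0)) {
    stop_ec("invalid_measurement", "birth weight must be positive")
  }
  ga_cat <- factor(ifelse(is.na(gestational_age), NA_character_,
                   ifelse(gestational_age < 37, "preterm",
                   ifelse(gestational_age <= 42, "term", "postterm"))),
                   levels = c("preterm", "term", "postterm"))
  bw_cat <- factor(ifelse(is.na(birth_weight), NA_character_,
                   ifelse(birth_weight < 2500, "low",
                   ifelse(birth_weight <= 4500, "normal", "high"))),
                   levels = c("low", "normal", "high"))
  cuts <- if (empirical_percentiles) {
    stats::quantile(birthweight_z, c(0.10, 0.90), na.rm = TRUE, names = FALSE)
  } else {
    stats::qnorm(c(0.10, 0.90))
  }
  sga_cat <- factor(ifelse(is.na(birthweight_z), NA_character_,
                    ifelse(birthweight_z < cuts[1], "SGA",
                    ifelse(birthweight_z > cuts[2], "LGA", "AGA"))),
                    levels = c("SGA", "AGA", "LGA"))
  data.frame(ga_cat = ga_cat, bw_cat = bw_cat, sga_cat = sga_cat)
}

change_levels <- function() c("deceleration", "normal", "acceleration")

classify_delta <- function(delta, threshold = 0.67) {
  factor(ifelse(is.na(delta), NA_character_,
         ifelse(delta > threshold, "acceleration",
         ifelse(delta < -threshold, "deceleration", "normal"))),
         levels = change_levels())
}

#' Fetal weight-change category
#'
#' Growth between the second trimester and birth: the change in SD score,
#' categorized as acceleration (> `threshold`), deceleration
#' (< `-threshold`), or normal otherwise. Missing scores yield `NA`
#' (subjects are excluded from pattern analyses and counted by the caller).
#'
#' @param z_t2 Second-trimester weight SD score.
#' @param z_birth Birth-weight SD score.
#' @param threshold Change threshold in SD-score units; 0.67 corresponds to
#'   crossing two percentile lines on a growth chart.
#' @return Data frame with `delta_sd` and factor `category`.
#' @export
fetal_change <- function(z_t2, z_birth, threshold = 0.67) {
  delta <- z_birth - z_t2
  data.frame(delta_sd = delta, category = classify_delta(delta, threshold))
}

#' Infant weight-change category with endpoint fallback
#'
#' Growth from birth to 24 months; when the 24-month score is missing the
#' change is computed to 12 months, then 6 months (endpoint order
#' 24 -> 12 -> 6, never the reverse). The endpoint actually used is recorded.
#'
#' @param z_birth Birth-weight SD score.
#' @param z_m6,z_m12,z_m24 Infant weight SD scores.
#' @param threshold Change threshold in SD-score units.
#' @return Data frame with `delta_sd`, factor `category`, and factor
#'   `endpoint` (`m24`, `m12`, `m6`, or `none`).
#' @export
infant_change <- function(z_birth, z_m6, z_m12, z_m24, threshold = 0.67) {
  n <- max(length(z_birth), length(z_m6), length(z_m12), length(z_m24))
  z_birth <- rep_len(z_birth, n); z_m6 <- rep_len(z_m6, n)
  z_m12 <- rep_len(z_m12, n); z_m24 <- rep_len(z_m24, n)
  endpoint <- ifelse(!is.na(z_m24), "m24",
              ifelse(!is.na(z_m12), "m12",
              ifelse(!is.na(z_m6), "m6", "none")))
  z_end <- ifelse(endpoint == "m24", z_m24,
           ifelse(endpoint == "m12", z_m12,
           ifelse(endpoint == "m6", z_m6, NA_real_)))
  delta <- z_end - z_birth
  data.frame(delta_sd = delta,
             category = classify_delta(delta, threshold),
             endpoint = factor(endpoint, levels = c("m24", "m12", "m6", "none")))
}

#' Combine fetal and infant change categories into the 9-level pattern
#'
#' The cross of the two 3-level categories; the reference group is normal
#' fetal growth followed by normal infant growth.
#'
#' @param fetal,infant Factors (or characters) with levels
#'   deceleration/normal/acceleration.
#' @return Data frame with factor `pattern9` (reference level first) and
#'   logical `is_reference`. Unresolved categories give `NA`.
#' @export
combine_patterns <- function(fetal, infant) {
  fetal <- as.character(fetal); infant <- as.character(infant)
  lv <- pattern9_levels()
  lab <- ifelse(is.na(fetal) | is.na(infant), NA_character_,
                paste0("fetal ", fetal, " / infant ", infant))
  pattern9 <- factor(lab, levels = lv)
  data.frame(pattern9 = pattern9,
             is_reference = !is.na(lab) & lab == lv[1])
}

#' The nine growth-pattern labels, reference group first
#' @return Character vector of 9 labels.
#' @export
pattern9_levels <- function() {
  ref <- "fetal normal / infant normal"
  all9 <- as.vector(outer(change_levels(), change_levels(),
                          function(f, i) paste0("fetal ", f, " / infant ", i)))
  c(ref, setdiff(all9, ref))
}

#' Append growth-classification columns to a wide per-subject table
#'
#' Convenience wrapper running [classify_birth_outcomes()], [fetal_change()],
#' [infant_change()] and [combine_patterns()] over a wide table with columns
#' `ga_birth`, `birth_weight_g`, `z_t2`, `z_birth`, `z_m6`, `z_m12`, `z_m24`.
#'
#' @param wide Wide per-subject data frame.
#' @param threshold Change threshold in SD-score units.
#' @return `wide` with appended columns `ga_cat`, `bw_cat`, `sga_cat`,
#'   `fetal_change`, `infant_change`, `infant_endpoint`, `pattern9`, plus a
#'   `"classification_counts"` attribute logging category and fallback
#'   endpoint counts.
#' @export
growth_features <- function(wide, threshold = 0.67) {
  bo <- classify_birth_outcomes(wide$ga_birth, wide$birth_weight_g, wide$z_birth)
  fc <- fetal_change(wide$z_t2, wide$z_birth, threshold)
  ic <- infant_change(wide$z_birth, wide$z_m6, wide$z_m12, wide$z_m24, threshold)
  cp <- combine_patterns(fc$category, ic$category)
  wide$ga_cat <- bo$ga_cat
  wide$bw_cat <- bo$bw_cat
  wide$sga_cat <- bo$sga_cat
  wide$fetal_change <- fc$category
  wide$infant_change <- ic$category
  wide$infant_endpoint <- ic$endpoint
  wide$pattern9 <- cp$pattern9
  counts <- list(
    ga_cat = table(bo$ga_cat, useNA = "ifany"),
    bw_cat = table(bo$bw_cat, useNA = "ifany"),
    sga_cat = table(bo$sga_cat, useNA = "ifany"),
    fetal_change = table(fc$category, useNA = "ifany"),
    infant_change = table(ic$category, useNA = "ifany"),
    infant_endpoint = table(ic$endpoint),
    pattern_missing = sum(is.na(cp$pattern9))
  )
  attr(wide, "classification_counts") <- counts
  wide
}
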