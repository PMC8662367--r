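#!/usr/bin/env Rscript
# Stage 3: the four association analyses, complete-case, confounder tier.
#
# 1. Birth outcomes (gestational age, birth weight, size for gestational
#    age, continuous and categorical) vs brain outcomes.
# 2. Critical periods: conditional growth variables per occasion.
# 3. The nine fetal-by-infant growth patterns vs the normal/normal group.
# 4. Infant growth parameters: PWV, BMI and age at adiposity peak.
# Plus sex-interaction and nonlinearity checks for the main exposure.

library(earlygrowth)

long <- read.csv("results/cohort_long.csv", na.strings = c("", "NA"))
bmi <- read.csv("results/cohort_bmi.csv", na.strings = c("", "NA"))
wide <- read.csv("results/cohort_wide.csv", na.strings = c("", "NA"))
cohort <- list(long = long, bmi = bmi, wide = wide)

res <- run_pipeline(cohort, tier = "confounder", seed = 1)
print(res)

for (nm in names(res$tables)) {
  tab <- res$tables[[nm]]
  write.csv(tab, sprintf("results/table_%s.csv", nm), row.names = FALSE, na = "")
  fmt <- format_assoc_table(tab)
  writeLines(capture.output(print(fmt, row.names = FALSE)),
             sprintf("results/table_%s.txt", nm))
}

tbv <- res$tables$birth_outcomes
zrow <- tbv[tbv$exposure == "z_birth" & tbv$outcome == "total_brain_volume", ]
cat(sprintf("\nTotal brain volume per birth-weight SD score: %.1f cm^3 (95%% CI %.1f to %.1f), n = %d.\n",
            zrow$estimate, zrow$ci_lo, zrow$ci_hi, zrow$n))

feats <- res$features
covs <- tier_covariates("confounder")
sx <- test_sex_interaction(feats, "total_brain_volume", "z_birth",
                           covariates = covs)
nl <- test_nonlinearity(feats, "total_brain_volume", "z_birth",
                        covariates = covs)
cat(sprintf("Sex interaction p = %.3f (no interaction generated).\n", sx$p))
cat(sprintf("Nonlinearity p = %.3f; the generated dose-response is linear in the\n", nl$p))
cat("latent score, but estimated SD scores are gestational-age-modulated, so a\n")
cat("small curvature against the estimated exposure can legitimately appear.\n")
cat("Wrote results/table_*.csv and .txt\n")
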