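#!/usr/bin/env Rscript
# Stage 4: the same birth-outcome analysis with multiply imputed covariates.
#
# Covariates (never exposures or outcomes) are imputed by chained equations,
# 30 completed datasets; per-imputation estimates are pooled with Rubin's
# rules. Compare the pooled table with the complete-case table of stage 3:
# the point estimates should agree while the analysis n returns to the full
# cohort.

library(earlygrowth)

long <- read.csv("results/cohort_long.csv", na.strings = c("", "NA"))
bmi <- read.csv("results/cohort_bmi.csv", na.strings = c("", "NA"))
wide <- read.csv("results/cohort_wide.csv", na.strings = c("", "NA"))
cohort <- list(long = long, bmi = bmi, wide = wide)

res <- run_pipeline(cohort, tier = "confounder", impute = TRUE, m = 30,
                    analyses = "birth_outcomes",
                    outcomes = "total_brain_volume", seed = 2)
tab <- res$tables$birth_outcomes
write.csv(tab, "results/table_birth_outcomes_pooled.csv",
          row.names = FALSE, na = "")
writeLines(capture.output(print(format_assoc_table(tab), row.names = FALSE)),
           "results/table_birth_outcomes_pooled.txt")

cc <- tryCatch(read.csv("results/table_birth_outcomes.csv"),
               error = function(e) NULL)
zrow <- tab[tab$exposure == "z_birth", ]
cat(sprintf("Pooled (m = 30): %.1f cm^3 per birth-weight SD (95%% CI %.1f to %.1f), n = %d.\n",
            zrow$estimate, zrow$ci_lo, zrow$ci_hi, zrow$n))
if (!is.null(cc)) {
  cz <- cc[cc$exposure == "z_birth" & cc$outcome == "total_brain_volume", ]
  cat(sprintf("Complete-case counterpart: %.1f cm^3, n = %d.\n",
              cz$estimate, cz$n))
}
cat("Wrote results/table_birth_outcomes_pooled.{csv,txt}\n")
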