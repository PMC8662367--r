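# Tiered association models, sex interaction, nonlinearity check, tables.

sim_assoc <- function(n = 1500, beta = 20, sigma = 50, seed = 1,
                      sex_slopes = c(female = beta, male = beta)) {
  set.seed(seed)
  sex <- rep(c("female", "male"), length.out = n)
  z <- rnorm(n)
  age <- rnorm(n, 10.1, 0.6)
  y <- 1000 + unname(sex_slopes[sex]) * z + 30 * (sex == "male") +
    rnorm(n, 0, sigma)
  data.frame(sex = sex, age_mri = age, z_birth = z, vol = y)
}

test_that("a simulated linear effect is estimated with correct CI behaviour", {
  d <- sim_assoc(n = 3000, beta = 20, seed = 42)
  r <- fit_association(d, "vol", "z_birth", covariates = c("sex", "age_mri"),
                       tier = "basic")
  expect_s3_class(r, "association_result")
  expect_equal(nrow(r), 1)
  expect_lt(abs(r$estimate - 20), 3 * r$se)
  expect_equal(r$ci_lo, r$estimate - 1.96 * r$se)
  expect_equal(r$ci_hi, r$estimate + 1.96 * r$se)
  expect_equal(r$n, 3000)
  expect_lt(r$p, 0.001)
})

test_that("degenerate designs and unresolvable variables are rejected", {
  d <- sim_assoc(n = 200)
  d$const <- 1
  expect_error(fit_association(d, "vol", "const"), class = "collinearity_error")
  d$dup <- d$z_birth
  expect_error(fit_association(d, "vol", "z_birth", covariates = "dup"),
               class = "collinearity_error")
  expect_error(fit_association(d, "vol", "nope"),
               class = "configuration_error")
  expect_error(fit_association(d[1:8, ], "vol", "z_birth"),
               class = "insufficient_data")
})

test_that("categorical exposures contrast against the stated reference level", {
  set.seed(8)
  n <- 900
  g <- sample(c("SGA", "AGA", "LGA"), n, TRUE, prob = c(0.1, 0.8, 0.1))
  means <- c(SGA = -35, AGA = 0, LGA = 35)
  d <- data.frame(sex = rep(c("female", "male"), length.out = n),
                  g = g, vol = 1000 + means[g] + rnorm(n, 0, 40))
  r <- fit_association(d, "vol", "g", covariates = "sex", reference = "AGA")
  expect_equal(nrow(r), 3)
  expect_equal(r$level[1], "AGA")
  expect_true(is.na(r$estimate[1])) # reference row
  est <- setNames(r$estimate[-1], r$level[-1])
  expect_lt(abs(est[["SGA"]] - (-35)), 12)
  expect_lt(abs(est[["LGA"]] - 35), 12)
  expect_error(fit_association(d, "vol", "g", reference = "XGA"),
               class = "configuration_error")
})

test_that("sex-interaction test detects differing slopes and rejects single-sex data", {
  d_eq <- sim_assoc(n = 1200, seed = 3)
  p_eq <- test_sex_interaction(d_eq, "vol", "z_birth",
                               covariates = c("sex", "age_mri"))$p
  expect_gt(p_eq, 0.001) # no real interaction most of the time
  d_ne <- sim_assoc(n = 3000, seed = 4,
                    sex_slopes = c(female = 20, male = 40))
  r_ne <- test_sex_interaction(d_ne, "vol", "z_birth",
                               covariates = c("sex", "age_mri"))
  expect_lt(r_ne$p, 0.01)
  expect_lt(abs(r_ne$estimate - 20), 4 * r_ne$se)
  single <- subset(d_eq, sex == "female")
  expect_error(test_sex_interaction(single, "vol", "z_birth"),
               class = "degenerate_design")
})

test_that("nonlinearity check keeps size under a linear truth and power under a quadratic", {
  set.seed(5)
  reps <- 120
  p_lin <- p_quad <- numeric(reps)
  for (i in seq_len(reps)) {
    n <- 400
    x <- rnorm(n)
    y_lin <- 10 * x + rnorm(n, 0, 5)
    y_quad <- 10 * x + 4 * x^2 + rnorm(n, 0, 5)
    d <- data.frame(x = x, y1 = y_lin, y2 = y_quad)
    p_lin[i] <- test_nonlinearity(d, "y1", "x")$p
    p_quad[i] <- test_nonlinearity(d, "y2", "x")$p
  }
  expect_lt(mean(p_lin < 0.05), 0.15)  # near-nominal size (crude at 120 reps)
  expect_gt(mean(p_quad < 0.05), 0.9)  # strong quadratic is detected
  two_vals <- data.frame(x = rep(0:1, 50), y = rnorm(100))
  expect_error(test_nonlinearity(two_vals, "y", "x"),
               class = "insufficient_variation")
})

test_that("confounder adjustment removes bias that the basic tier retains", {
  # analytic omitted-variable bias: regressing y on z while omitting x
  # inflates the slope by g * cov(x, z) / var(z)
  set.seed(6)
  n <- 4000
  p <- 0.204; alpha <- -0.6; g <- -40; beta <- 20
  x <- rbinom(n, 1, p)
  z <- alpha * x + rnorm(n)
  y <- beta * z + g * x + rnorm(n, 0, 50)
  d <- data.frame(z = z, y = y, x = factor(ifelse(x == 1, "yes", "no")))
  b_basic <- fit_association(d, "y", "z")$estimate
  b_conf <- fit_association(d, "y", "z", covariates = "x")$estimate
  bias_true <- g * alpha * p * (1 - p) / (alpha^2 * p * (1 - p) + 1)
  expect_gt(bias_true, 0)
  expect_lt(abs(b_conf - beta), 2.5)              # adjusted: unbiased
  expect_lt(abs((b_basic - beta) - bias_true), 2) # unadjusted: biased as derived
  expect_gt(b_basic, b_conf)                      # bias in the generated direction
})

test_that("run_table is deterministic with the documented row layout", {
  d <- sim_assoc(n = 600, seed = 7)
  d$g <- sample(c("a", "b", "c"), 600, TRUE)
  t1 <- run_table(d, outcomes = c("vol"), exposures = c("z_birth", "g"),
                  covariates = c("sex", "age_mri"),
                  references = c(g = "b"), tier = "basic")
  expect_equal(nrow(t1), 1 + 3) # 1 continuous + ref row + 2 contrasts
  t2 <- run_table(d, outcomes = c("vol"), exposures = c("z_birth", "g"),
                  covariates = c("sex", "age_mri"),
                  references = c(g = "b"), tier = "basic")
  expect_identical(t1, t2)
  fm <- format_assoc_table(t1)
  expect_equal(fm$difference[t1$exposure == "g" & t1$level == "b"],
               "[Reference]")
  expect_true(any(grepl("\\*\\*$", fm$difference))) # strong effect starred
})

test_that("tier covariate sets form a superset chain", {
  b <- tier_covariates("basic")
  c1 <- tier_covariates("confounder")
  c2 <- tier_covariates("bmi")
  expect_true(all(b %in% c1))
  expect_true(all(c1 %in% c2))
  expect_true("child_bmi_z" %in% setdiff(c2, c1))
})
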