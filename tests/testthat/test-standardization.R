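# Hadlock estimated fetal weight, internal reference fitting, SD scores,
# external reference files.

test_that("Hadlock formula reproduces the published model and its edge cases", {
  # hand evaluation of 10^(1.326 - 0.00326*16*3 + 0.0107*20 + 0.0438*16 + 0.158*3)
  expect_equal(estimate_fetal_weight(20, 16, 3), 361.676257, tolerance = 1e-8)
  # constant model: all coefficients zero except the intercept
  k0 <- list(c0 = log10(1000), c1 = 0, c2 = 0, c3 = 0, c4 = 0, version = "test")
  expect_equal(estimate_fetal_weight(5, 5, 5, k0), 1000)
  expect_equal(estimate_fetal_weight(30, 2, 9, k0), 1000)
  expect_error(estimate_fetal_weight(20, 0, 3), class = "invalid_measurement")
  expect_error(estimate_fetal_weight(20, 16, 3, coefficients = list(c0 = 1)),
               class = "configuration_error")
  expect_error(hadlock_coefficients("no-such-version"),
               class = "configuration_error")
})

test_that("estimated fetal weight is monotone in each biometry argument", {
  grid <- seq(1, 30, by = 0.5)
  base <- estimate_fetal_weight(20, 16, 3)
  # positive coefficients: hc, and fl/ac at small values where the positive
  # linear terms dominate the negative ac*fl cross term
  expect_true(all(diff(estimate_fetal_weight(grid, 16, 3)) > 0))
  k <- hadlock_coefficients()
  for (ac in c(5, 15, 25)) {
    fl <- seq(0.5, 5, by = 0.1)
    dw <- diff(estimate_fetal_weight(20, ac, fl))
    expect_true(all(dw > 0) == (k$c4 + k$c1 * ac > 0))
  }
  expect_gt(estimate_fetal_weight(20, 16, 3), 0)
  expect_gt(base, 0)
})

test_that("internal reference reproduces a noiseless growth law and flags zero dispersion", {
  d <- make_linear_cohort(n = 300, slope = 100, noise_sd = 0)
  ref <- fit_internal_reference(d, by_sex = FALSE, log_scale = FALSE)
  expect_s3_class(ref, "growth_reference")
  expect_true(ref$strata$all$degenerate)
  ages <- seq(19, 31, by = 0.5)
  mu <- 100 * ages
  z_hi <- sd_score(mu * 1.001, ages, ref)
  z_at <- sd_score(mu, ages, ref)
  # mu is recovered: points on the line score ~0 relative to points off it
  expect_true(all(abs(z_at) < abs(z_hi)))
})

test_that("internal reference recovers generating mean within 2% at interior ages", {
  set.seed(42)
  n <- 2000
  age <- runif(n, 18, 32)
  mu <- function(a) 50 * a^1.5 # smooth, curved truth
  sig <- function(a) 0.1 * mu(a)
  d <- data.frame(age = age, weight = mu(age) + sig(age) * rnorm(n))
  ref <- fit_internal_reference(d, by_sex = FALSE, log_scale = FALSE)
  interior <- seq(20, 30, by = 0.5)
  # scoring the true mean gives z0 = (mu_true - mu_fit)/sd_fit, and scoring
  # 1.02*mu_true gives z1 with z1 - z0 = 0.02*mu_true/sd_fit, so
  # |z0| < z1 - z0 is exactly |mu_fit - mu_true| < 2% of mu_true
  z0 <- sd_score(mu(interior), interior, ref)
  z1 <- sd_score(mu(interior) * 1.02, interior, ref)
  expect_true(all(abs(z0) < abs(z1 - z0)))
})

test_that("reference fitting enforces minimum stratum size", {
  d <- make_linear_cohort(n = 10)
  expect_error(fit_internal_reference(d, by_sex = FALSE),
               class = "insufficient_data")
  d2 <- make_linear_cohort(n = 60) # 30 per sex < 50
  expect_error(fit_internal_reference(d2, by_sex = TRUE, min_n = 50),
               class = "insufficient_data")
})

test_that("SD scores are zero at the mean, increasing in x, and error off-support", {
  set.seed(7)
  d <- data.frame(age = runif(500, 1, 24),
                  weight = 5 + 0.3 * runif(500, 1, 24) + rnorm(500, 0, 0.5))
  ref <- fit_internal_reference(d, by_sex = FALSE)
  xs <- seq(4, 14, by = 0.5)
  z <- sd_score(xs, rep(12, length(xs)), ref)
  expect_true(all(diff(z) > 0)) # strictly increasing in x at fixed age
  expect_error(sd_score(8, 30, ref), class = "range_error")
  expect_error(sd_score(8, 0.5, ref), class = "range_error")
  expect_true(is.na(sd_score(NA_real_, 12, ref)))
})

test_that("internally standardized scores have mean ~0 and SD ~1 per stratum", {
  set.seed(11)
  n <- 2000
  sex <- rep(c("female", "male"), length.out = n)
  age <- runif(n, 5, 28)
  base <- ifelse(sex == "male", 1.08, 1)
  w <- base * (4 + 0.4 * age) * exp(0.12 * rnorm(n))
  d <- data.frame(sex = sex, age = age, weight = w)
  ref <- fit_internal_reference(d, by_sex = TRUE, log_scale = FALSE)
  z <- sd_score(w, age, ref, sex = sex)
  for (s in c("female", "male")) {
    expect_lt(abs(mean(z[sex == s])), 0.02)
    expect_lt(abs(sd(z[sex == s]) - 1), 0.02)
  }
})

test_that("LMS scoring matches its closed-form reductions and the moments form", {
  grid <- data.frame(sex = "all", age = c(0, 12), L = 1, M = c(3.5, 9.6),
                     S = 0.1)
  ref <- read_external_reference(write_ref_file(grid))
  # L = 1 reduces to (x - M)/(M S); at age 6 interpolation gives M = 6.55
  x <- 7.205
  expect_equal(sd_score(x, 6, ref), (x - 6.55) / (6.55 * 0.1), tolerance = 1e-12)
  expect_equal(sd_score(6.55, 6, ref), 0, tolerance = 1e-12)
  # L = 0.5, x = M gives exactly 0
  grid2 <- data.frame(sex = "all", age = c(1, 2), L = 0.5, M = 10, S = 0.1)
  ref2 <- read_external_reference(write_ref_file(grid2))
  expect_equal(sd_score(10, 1.5, ref2), 0, tolerance = 1e-12)
  # |L| < 1e-6 uses the log-limit form
  grid3 <- data.frame(sex = "all", age = c(1, 2), L = 1e-9, M = 10, S = 0.1)
  ref3 <- read_external_reference(write_ref_file(grid3))
  expect_equal(sd_score(12, 1.5, ref3), log(12 / 10) / 0.1, tolerance = 1e-6)
  # LMS with L = 1, M = mu, M*S = sigma agrees exactly with the moments form
  mom <- data.frame(sex = "all", age = c(0, 12), mean = c(3.5, 9.6),
                    sd = 0.1 * c(3.5, 9.6))
  refm <- read_external_reference(write_ref_file(mom))
  xs <- c(3, 5, 8, 11)
  ages <- c(1, 4, 8, 11)
  expect_equal(sd_score(xs, ages, ref), sd_score(xs, ages, refm),
               tolerance = 1e-12)
})

test_that("external reference files are validated and round-trip exactly", {
  # linear interpolation midpoint example
  grid <- data.frame(sex = "all", age = c(0, 12), L = 1, M = c(3.5, 9.6), S = 0.1)
  ref <- read_external_reference(write_ref_file(grid))
  # sd = 0 row is a format error
  bad <- data.frame(sex = "all", age = c(0, 12), mean = c(3.5, 9.6), sd = c(0.4, 0))
  expect_error(read_external_reference(write_ref_file(bad)),
               class = "format_error")
  # malformed header
  malformed <- data.frame(sex = "all", age = c(0, 12), center = c(3.5, 9.6))
  expect_error(read_external_reference(write_ref_file(malformed)),
               class = "format_error")
  # non-monotone age grid
  nonmono <- data.frame(sex = "all", age = c(12, 0), L = 1, M = c(9.6, 3.5), S = 0.1)
  expect_error(read_external_reference(write_ref_file(nonmono)),
               class = "format_error")
  # round-trip write-then-read returns the identical grid
  out <- tempfile(fileext = ".csv")
  write_external_reference(ref, out)
  ref2 <- read_external_reference(out)
  expect_equal(ref2$strata$all$grid$M, ref$strata$all$grid$M)
  expect_equal(ref2$strata$all$grid$age, ref$strata$all$grid$age)
  expect_identical(ref2$form, ref$form)
  # sex-stratified reference requires the sex argument
  gs <- rbind(transform(grid, sex = "female"), transform(grid, sex = "male"))
  refs <- read_external_reference(write_ref_file(gs))
  expect_error(sd_score(5, 6, refs), class = "missing_stratum")
  expect_error(sd_score(5, 6, refs, sex = "unknown"), class = "missing_stratum")
  expect_equal(sd_score(6.55, 6, refs, sex = "female"), 0, tolerance = 1e-12)
})
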