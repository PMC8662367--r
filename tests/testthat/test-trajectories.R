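# Reed1 weight curve / peak weight velocity and the adiposity-peak cubic.

test_that("closed-form PWV matches its derivation and the numeric oracle", {
  r <- pwv_from_coefficients(b = 6, c = 1.2, d = 0.06)
  expect_equal(r$t_pwv, 0.1)           # t* = 2d/c
  expect_equal(r$pwv, 12.0)            # b + c^2/(4d) = 6 + 1.44/0.24
  o <- numeric_pwv(6, 1.2, 0.06)
  expect_equal(r$t_pwv, o$t_star, tolerance = 1e-6)
  expect_equal(r$pwv, o$pwv, tolerance = 1e-9)
  # c = d > 0 gives t* = 2 and pwv = b + c/4
  r2 <- pwv_from_coefficients(3, 0.8, 0.8)
  expect_equal(r2$t_pwv, 2)
  expect_equal(r2$pwv, 3 + 0.8 / 4)
  # no interior maximum when c <= 0 or d <= 0: flagged, not guessed
  bad <- pwv_from_coefficients(c(6, 6, 6), c(-1, 1, 0), c(0.1, -0.1, 0.2))
  expect_true(all(!bad$valid))
  expect_true(all(is.na(bad$pwv)))
})

test_that("closed-form PWV equals numeric maximization over random coefficients", {
  set.seed(100)
  n <- 300
  b <- runif(n, 0, 15)
  cc <- runif(n, 1e-3, 5)
  dd <- runif(n, 1e-3, 5)
  cf <- pwv_from_coefficients(b, cc, dd)
  for (i in seq_len(n)) {
    o <- numeric_pwv(b[i], cc[i], dd[i])
    expect_lt(abs(cf$t_pwv[i] - o$t_star) / o$t_star, 1e-6)
    expect_lt(abs(cf$pwv[i] - o$pwv) / max(abs(o$pwv), 1e-12), 1e-6)
  }
})

test_that("a noiseless single Reed1 curve is recovered to high precision", {
  truth <- c(a = 3.2, b = 6, c = 1.2, d = 0.06)
  t <- c(3 / 365.25, seq(0.1, 3, length.out = 11))
  d <- do.call(rbind, lapply(1:6, function(s) {
    data.frame(subject_id = sprintf("id%d", s), sex = "female",
               age_years = t,
               weight_kg = truth["a"] + truth["b"] * t +
                 truth["c"] * log(t) + truth["d"] / t)
  }))
  fit <- fit_reed1(d, random = "none")
  fe <- fit$by_sex$female$fixef
  expect_equal(unname(fe[["(Intercept)"]]), 3.2, tolerance = 1e-6)
  expect_equal(unname(fe[["t"]]), 6, tolerance = 1e-6)
  expect_equal(unname(fe[["lnt"]]), 1.2, tolerance = 1e-6)
  expect_equal(unname(fe[["invt"]]), 0.06, tolerance = 1e-6)
  expect_equal(fit$subjects$pwv[1], 12.0, tolerance = 1e-6)
  expect_equal(fit$subjects$t_pwv[1], 0.1, tolerance = 1e-6)
})

test_that("mixed Reed1 fit recovers generating fixed effects and mean PWV", {
  set.seed(21)
  n <- 400
  truth <- c(a = 8.0, b = 1.6, c = 1.75, d = 0.030)
  sd_a <- 0.5; sd_b <- 0.6; resid <- 0.3
  t_grid <- c(3 / 365.25, 0.25, 0.5, 1, 1.5, 2.5)
  rows <- lapply(seq_len(n), function(i) {
    ai <- truth["a"] + rnorm(1, 0, sd_a)
    bi <- truth["b"] + rnorm(1, 0, sd_b)
    data.frame(subject_id = sprintf("id%04d", i), sex = "male",
               age_years = t_grid,
               weight_kg = ai + bi * t_grid + truth["c"] * log(t_grid) +
                 truth["d"] / t_grid + rnorm(length(t_grid), 0, resid))
  })
  fit <- fit_reed1(do.call(rbind, rows), random = c("a", "b"))
  fe <- fit$by_sex$male$fixef
  expect_lt(abs(fe[["(Intercept)"]] - truth["a"]) / truth["a"], 0.05)
  expect_lt(abs(fe[["t"]] - truth["b"]) / truth["b"], 0.25) # small coef, looser
  expect_lt(abs(fe[["lnt"]] - truth["c"]) / truth["c"], 0.05)
  expect_lt(abs(fe[["invt"]] - truth["d"]) / truth["d"], 0.05)
  true_pwv <- truth["b"] + truth["c"]^2 / (4 * truth["d"])
  expect_lt(abs(mean(fit$subjects$pwv, na.rm = TRUE) - true_pwv), 0.3)
})

test_that("Reed1 input contracts are enforced", {
  d <- data.frame(subject_id = "a", sex = "female",
                  age_years = c(0.1, 0.5, 1, 2), weight_kg = c(4, 7, 9, 12))
  expect_error(fit_reed1(transform(d, age_years = c(0.1, 0.5, 1, 4))),
               class = "validation_error")
  expect_error(fit_reed1(d[, -4]), class = "schema_error")
  expect_error(fit_reed1(d[1:2, ], min_obs = 3), class = "insufficient_data")
  expect_error(fit_reed1(d, random = c("a", "nope")),
               class = "configuration_error")
})

test_that("adiposity peak selects the in-window maximum root", {
  # b1=0.9, b2=-0.6, b3=0.1: stationary points t = 1 and t = 3; the second
  # derivative at t=1 is -0.6 < 0, so the peak is 12 months
  pk <- adiposity_peak(0.9, -0.6, 0.1, window = c(14 / 365.25, 1.5))
  expect_true(pk$valid)
  expect_equal(pk$t_peak * 12, 12, tolerance = 1e-9)
  o <- numeric_cubic_peak(0.9, -0.6, 0.1)
  expect_equal(pk$t_peak, o, tolerance = 1e-8)
  # b3 ~ 0 falls back to the quadratic vertex -b1/(2 b2) = 2/3 y = 8 months
  pk2 <- adiposity_peak(0.2, -0.15, 0)
  expect_equal(pk2$t_peak * 12, 8, tolerance = 1e-9)
  # no admissible root -> flagged
  pk3 <- adiposity_peak(-0.5, -0.2, 0)     # monotone decreasing
  expect_false(pk3$valid)
  pk4 <- adiposity_peak(0.9, -0.6, 0.1, window = c(1.2, 1.5)) # peak outside
  expect_false(pk4$valid)
})

test_that("analytic cubic peaks equal numeric maximization on random cubics", {
  set.seed(200)
  n <- 300
  hits <- 0
  for (i in seq_len(n)) {
    b3 <- runif(1, 0.05, 0.6)
    tpk <- runif(1, 0.1, 1.3)
    t2nd <- runif(1, 1.6, 4) # second stationary point outside the window
    # derivative 3 b3 (t - tpk)(t - t2nd): expand to get b1, b2
    b2 <- -3 * b3 * (tpk + t2nd) / 2
    b1 <- 3 * b3 * tpk * t2nd
    pk <- adiposity_peak(b1, b2, b3)
    o <- numeric_cubic_peak(b1, b2, b3)
    expect_true(pk$valid)
    expect_lt(abs(pk$t_peak - o), 1e-8)
    hits <- hits + 1
  }
  expect_equal(hits, n)
})

test_that("noiseless cohort from a known cubic returns exact per-subject peaks", {
  set.seed(30)
  n <- 60
  beta <- c(b0 = 2.53, b1 = 1.07, b2 = -0.979, b3 = 0.204)
  b1_i <- rnorm(n, 0, 0.04)
  tv <- c(0.06, 0.25, 0.6, 0.95, 1.3)
  rows <- lapply(seq_len(n), function(i) {
    lb <- beta["b0"] + (beta["b1"] + b1_i[i]) * tv + beta["b2"] * tv^2 +
      beta["b3"] * tv^3
    data.frame(subject_id = sprintf("id%03d", i), sex = "female",
               age_years = tv, bmi = exp(lb))
  })
  fit <- fit_adiposity_curve(do.call(rbind, rows))
  truth <- adiposity_peak(beta["b1"] + b1_i, beta["b2"], beta["b3"])
  ord <- match(sprintf("id%03d", seq_len(n)), fit$subjects$subject_id)
  expect_true(all(fit$subjects$valid[ord]))
  expect_equal(fit$subjects$age_at_peak[ord], truth$t_peak * 12,
               tolerance = 1e-4)
  # analytic identity at machine-level precision for the fitted coefficients
  re_peaks <- adiposity_peak(fit$subjects$b1[ord], fit$subjects$b2[ord][1],
                             fit$subjects$b3[ord][1])
  expect_equal(fit$subjects$age_at_peak[ord], re_peaks$t_peak * 12,
               tolerance = 1e-8)
})

test_that("adiposity fit recovers generating fixed effects with noise", {
  set.seed(31)
  n <- 500
  beta <- c(b0 = 2.528, b1 = 1.07, b2 = -0.979, b3 = 0.204)
  sexes <- rep(c("female", "male"), length.out = n)
  b0_i <- rnorm(n, 0, 0.045); b1_i <- rnorm(n, 0, 0.042)
  tv <- c(0.05, 0.2, 0.45, 0.8, 1.1, 1.4)
  rows <- lapply(seq_len(n), function(i) {
    lb <- beta["b0"] + 0.012 * (sexes[i] == "male") + b0_i[i] +
      (beta["b1"] + b1_i[i]) * tv + beta["b2"] * tv^2 + beta["b3"] * tv^3 +
      rnorm(length(tv), 0, 0.025)
    data.frame(subject_id = sprintf("id%04d", i), sex = sexes[i],
               age_years = tv, bmi = exp(lb))
  })
  fit <- fit_adiposity_curve(do.call(rbind, rows))
  expect_lt(abs(fit$fixef[["(Intercept)"]] - beta["b0"]), 0.02)
  expect_lt(abs(fit$fixef[["t"]] - beta["b1"]), 0.08)
  expect_lt(abs(fit$fixef[["t2"]] - beta["b2"]), 0.15)
  expect_lt(abs(fit$fixef[["t3"]] - beta["b3"]), 0.10)
  med <- median(fit$subjects$age_at_peak, na.rm = TRUE)
  expect_gt(med, 7.8)
  expect_lt(med, 9.6)
})

test_that("adiposity input contracts are enforced", {
  d <- data.frame(subject_id = "a", sex = "f", age_years = c(0.1, 0.5, 1),
                  bmi = c(14, 17, 17.5))
  expect_error(fit_adiposity_curve(transform(d, bmi = c(14, -1, 17))),
               class = "invalid_measurement")
  expect_error(fit_adiposity_curve(d[, -4]), class = "schema_error")
  expect_error(fit_adiposity_curve(d[1, , drop = FALSE]),
               class = "insufficient_data")
})
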