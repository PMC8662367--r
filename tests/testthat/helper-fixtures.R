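# Shared fixtures: all built in code at test time.

# A minimal long table on an exact growth law, for reference-fitting tests.
make_linear_cohort <- function(n = 200, slope = 100, noise_sd = 0, seed = 1) {
  set.seed(seed)
  age <- runif(n, 18, 32)
  data.frame(subject_id = sprintf("s%04d", seq_len(n)),
             sex = rep(c("female", "male"), length.out = n),
             age = age,
             weight = slope * age + rnorm(n, 0, noise_sd))
}

# Write a small external reference chart and return its path.
write_ref_file <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Numeric maximization oracle for the Reed1 velocity v(t) = b + c/t - d/t^2.
# On the reciprocal scale v(u) = b + c*u - d*u^2 is an exact parabola, so the
# vertex of the quadratic interpolant through any three sampled points is the
# maximizer to rounding error. Uses only function evaluations; independent of
# the closed forms it checks.
numeric_pwv <- function(b, c, d) {
  stopifnot(c > 0, d > 0)
  v <- function(u) b + c * u - d * u^2
  upper <- c / d # v(upper) = v(0): the maximum lies inside (0, upper)
  u3 <- upper * c(0.25, 0.5, 0.75)
  f3 <- v(u3)
  h <- u3[2] - u3[1]
  u_star <- u3[2] + h * (f3[1] - f3[3]) / (2 * (f3[1] - 2 * f3[2] + f3[3]))
  list(t_star = 1 / u_star, pwv = v(u_star))
}

# Numeric maximization oracle for a cubic f(t) = b1 t + b2 t^2 + b3 t^3 on a
# window: dense grid bracket, then finite-difference Newton refinement (the
# central second difference is exact for a cubic; the first-difference error
# is O(b3 h^2), negligible at h = 1e-5).
numeric_cubic_peak <- function(b1, b2, b3, window = c(14 / 365.25, 1.5)) {
  f <- function(t) b1 * t + b2 * t^2 + b3 * t^3
  grid <- seq(window[1], window[2], length.out = 4001)
  i <- which.max(f(grid))
  if (i == 1 || i == length(grid)) return(NA_real_) # boundary, no interior max
  t0 <- grid[i]
  h <- 1e-5
  for (k in 1:4) {
    g1 <- (f(t0 + h) - f(t0 - h)) / (2 * h)
    g2 <- (f(t0 + h) - 2 * f(t0) + f(t0 - h)) / h^2
    if (g2 >= 0) break
    t0 <- t0 - g1 / g2
  }
  t0
}
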