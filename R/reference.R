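# Reference growth models and SD-score computation.
#
# A `growth_reference` is either fitted internally from the cohort itself
# (moments form: smooth mean and SD as functions of age, optionally on the
# log scale and/or stratified by sex) or read from an external chart file
# (tabulated LMS or mean/sd grids with linear interpolation). Evaluation
# outside the supported age range is always an error, never extrapolation,
# because percentile cutoffs (SGA/LGA) are sensitive to tail behaviour.

#' Fit an internal growth reference from cohort data
#'
#' Fits a moments-form reference: the age-specific mean \eqn{\mu(age)} by a
#' natural cubic spline regression of (optionally log-transformed) weight on
#' age, and the age-specific SD \eqn{\sigma(age)} by a spline fit to absolute
#' residuals scaled by \eqn{\sqrt{\pi/2}} (the factor that makes the mean
#' absolute deviation of a normal equal its SD).
#'
#' @param data Data frame with columns `age`, `weight`, and `sex` when
#'   `by_sex = TRUE`.
#' @param by_sex Fit separate references per sex? Fetal references are
#'   conventionally unstratified (gestational-age adjustment only); birth and
#'   infant references are sex-specific.
#' @param log_scale Model `log(weight)` instead of raw weight. Appropriate
#'   for fetal weight, whose dispersion grows with gestation.
#' @param n_knots Number of interior spline knots, placed at quantiles.
#' @param min_n Minimum observations per stratum.
#' @return A `growth_reference` object.
#' @export
fit_internal_reference <- function(data, by_sex = FALSE, log_scale = FALSE,
                                   n_knots = 4, min_n = 50) {
  need <- c("age", "weight", if (by_sex) "sex")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ec("schema_error", "reference data lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  data <- data[!is.na(data$age) & !is.na(data$weight), , drop = FALSE]
  assert_numeric(data$age, "age", positive = TRUE)
  assert_numeric(data$weight, "weight", positive = TRUE)
  groups <- if (by_sex) split(data, as.character(data$sex)) else list(all = data)

  strata <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < min_n) {
      stop_ec("insufficient_data",
              "stratum '%s' has %d observations; need at least %d",
              g, nrow(d), min_n)
    }
    y <- if (log_scale) log(d$weight) else d$weight
    bs <- ns_quantile_basis(d$age, n_knots = n_knots)
    X <- cbind(1, bs$basis)
    mu_fit <- stats::lm.fit(X, y)
    res <- y - X %*% mu_fit$coefficients
    ay <- abs(res) * sqrt(pi / 2)
    # dispersion varies more smoothly than the mean: a stiffer spline avoids
    # tail wiggle where observations are sparse, and predictions are floored
    # at a fraction of the stratum's typical sigma to stay positive
    bs_sd <- ns_quantile_basis(d$age, n_knots = min(2, n_knots))
    Xs <- cbind(1, bs_sd$basis)
    sd_fit <- stats::lm.fit(Xs, ay)
    sd_hat <- drop(Xs %*% sd_fit$coefficients)
    sd_floor <- 0.25 * stats::median(pmax(sd_hat, 0))
    degenerate <- stats::sd(res) < 1e-8 * max(stats::sd(y), 1e-12)
    list(mu_coef = mu_fit$coefficients, sd_coef = sd_fit$coefficients,
         knots = bs$knots, boundary = bs$boundary,
         sd_knots = bs_sd$knots, sd_boundary = bs_sd$boundary,
         sd_floor = sd_floor,
         range = range(d$age), n = nrow(d), degenerate = degenerate)
  })
  names(strata) <- names(groups)
  structure(list(form = "moments_fit", by_sex = by_sex, log_scale = log_scale,
                 strata = strata, provenance = "internal-fit"),
            class = "growth_reference")
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("<growth_reference> form=%s, provenance=%s, strata: %s\n",
              x$form, x$provenance, paste(names(x$strata), collapse = ", ")))
  for (g in names(x$strata)) {
    s <- x$strata[[g]]
    cat(sprintf("  %s: age range [%.3g, %.3g]%s%s\n", g,
                s$range[1], s$range[2],
                if (!is.null(s$n)) sprintf(", n=%d", s$n) else "",
                if (isTRUE(s$degenerate)) " [degenerate: ~zero dispersion]" else ""))
  }
  invisible(x)
}

ref_stratum <- function(reference, sex) {
  if (!reference$by_sex) {
    return(reference$strata[["all"]])
  }
  if (is.null(sex) || anyNA(sex)) {
    stop_ec("missing_stratum", "reference is sex-stratified; `sex` is required")
  }
  sex <- as.character(sex)
  if (!all(sex %in% names(reference$strata))) {
    stop_ec("missing_stratum", "no reference stratum for sex '%s'",
            paste(setdiff(unique(sex), names(reference$strata)), collapse = "', '"))
  }
  sex
}

check_support <- function(age, rng) {
  tol <- 1e-8 * max(1, abs(rng))
  if (any(age < rng[1] - tol | age > rng[2] + tol)) {
    stop_ec("range_error",
            "age outside reference support [%.4g, %.4g]", rng[1], rng[2])
  }
}

eval_moments_fit <- function(stratum, age) {
  check_support(age, stratum$range)
  B <- splines::ns(age, knots = stratum$knots,
                   Boundary.knots = stratum$boundary)
  mu <- drop(cbind(1, B) %*% stratum$mu_coef)
  Bs <- splines::ns(age, knots = stratum$sd_knots,
                    Boundary.knots = stratum$sd_boundary)
  sdv <- drop(cbind(1, Bs) %*% stratum$sd_coef)
  sdv <- pmax(sdv, stratum$sd_floor, 1e-12)
  list(mu = mu, sd = sdv)
}

interp_cols <- function(grid, age, cols) {
  check_support(age, range(grid$age))
  out <- lapply(cols, function(cl) {
    stats::approx(grid$age, grid[[cl]], xout = age, rule = 1)$y
  })
  names(out) <- cols
  out
}

#' Compute SD scores against a growth reference
#'
#' Moments-form references give \eqn{z = (x - \mu(age))/\sigma(age)} (on the
#' log scale when the reference was fitted to log weight). LMS references use
#' \eqn{z = ((x/M)^L - 1)/(L\,S)}, with the limiting form
#' \eqn{z = \log(x/M)/S} when \eqn{|L| < 10^{-6}}.
#'
#' @param x Measurement (same units the reference was built on).
#' @param age Age on the reference's age axis.
#' @param reference A `growth_reference`.
#' @param sex Sex values, required for sex-stratified references.
#' @return Numeric vector of SD scores. `NA` inputs give `NA` scores.
#' @export
sd_score <- function(x, age, reference, sex = NULL) {
  stopifnot(inherits(reference, "growth_reference"))
  n <- max(length(x), length(age))
  x <- rep_len(x, n)
  age <- rep_len(age, n)
  if (reference$by_sex && is.null(sex)) {
    stop_ec("missing_stratum", "reference is sex-stratified; `sex` is required")
  }
  if (!is.null(sex)) sex <- rep_len(as.character(sex), n)
  z <- rep(NA_real_, n)
  ok <- !is.na(x) & !is.na(age) & if (reference$by_sex) !is.na(sex) else TRUE
  if (!any(ok)) return(z)
  assert_numeric(x[ok], "x", positive = TRUE)
  assert_numeric(age[ok], "age", positive = TRUE)

  strat_of <- if (reference$by_sex) ref_stratum(reference, sex[ok]) else
    rep("all", sum(ok))
  idx <- which(ok)
  for (g in unique(strat_of)) {
    sel <- idx[strat_of == g]
    s <- reference$strata[[g]]
    if (reference$form == "moments_fit") {
      ev <- eval_moments_fit(s, age[sel])
      xx <- if (reference$log_scale) log(x[sel]) else x[sel]
      z[sel] <- (xx - ev$mu) / ev$sd
    } else if (reference$form == "moments_table") {
      ev <- interp_cols(s$grid, age[sel], c("mean", "sd"))
      z[sel] <- (x[sel] - ev$mean) / ev$sd
    } else if (reference$form == "lms_table") {
      ev <- interp_cols(s$grid, age[sel], c("L", "M", "S"))
      L <- ev$L; M <- ev$M; S <- ev$S
      small <- abs(L) < 1e-6
      zz <- ((x[sel] / M)^L - 1) / (L * S)
      zz[small] <- log(x[sel][small] / M[small]) / S[small]
      z[sel] <- zz
    } else {
      stop_ec("configuration_error", "unknown reference form '%s'",
              reference$form)
    }
  }
  z
}

#' Read an external growth reference file
#'
#' Accepts delimited files in two dialects: LMS grids with header columns
#' `sex, age, L, M, S`, or moments grids with `sex, age, mean, sd`. A `sex`
#' value of `"all"` denotes an unstratified chart. Grid ages must be strictly
#' increasing within each stratum; evaluation interpolates linearly between
#' grid ages and errors outside them.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @return A `growth_reference` with provenance `"external-file"`.
#' @export
read_external_reference <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  lms <- c("sex", "age", "L", "M", "S")
  mom <- c("sex", "age", "mean", "sd")
  form <- if (all(lms %in% names(tab))) "lms_table"
          else if (all(mom %in% names(tab))) "moments_table"
          else stop_ec("format_error",
                       "header must contain {sex, age, L, M, S} or {sex, age, mean, sd}")
  vals <- if (form == "lms_table") c("M", "S") else c("sd")
  for (cl in c("age", vals)) {
    if (!is.numeric(tab[[cl]]) || anyNA(tab[[cl]])) {
      stop_ec("format_error", "column '%s' must be numeric and complete", cl)
    }
  }
  for (cl in vals) {
    if (any(tab[[cl]] <= 0)) {
      stop_ec("format_error", "column '%s' must be strictly positive", cl)
    }
  }
  strata <- lapply(split(tab, as.character(tab$sex)), function(d) {
    if (any(diff(d$age) <= 0)) {
      stop_ec("format_error", "age grid must be strictly increasing per stratum")
    }
    list(grid = d, range = range(d$age), n = nrow(d))
  })
  by_sex <- !identical(names(strata), "all")
  structure(list(form = form, by_sex = by_sex, log_scale = FALSE,
                 strata = strata, provenance = "external-file"),
            class = "growth_reference")
}

#' Write a tabulated growth reference back to a file
#'
#' Round-trips the grids of a tabulated (`lms_table` or `moments_table`)
#' reference so charts can be shared between analyses.
#'
#' @param reference A tabulated `growth_reference`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_external_reference <- function(reference, path) {
  stopifnot(inherits(reference, "growth_reference"))
  if (!reference$form %in% c("lms_table", "moments_table")) {
    stop_ec("configuration_error", "only tabulated references can be written")
  }
  grids <- do.call(rbind, lapply(reference$strata, `[[`, "grid"))
  rownames(grids) <- NULL
  utils::write.csv(grids, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
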