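# Multiple imputation of covariates by chained equations, and Rubin's rules.
#
# Each incomplete covariate is visited in turn and its missing entries drawn
# from a fitted conditional model given all other variables: Bayesian linear
# regression draws for continuous variables, logistic draws for binary
# factors, multinomial probability draws for unordered factors with more
# than two levels. Analysis variables (exposures, outcomes) are protected:
# they are never imputed, and missingness in them is an error. Observed
# cells are never altered.

draw_continuous <- function(y, X) {
  obs <- !is.na(y)
  qrX <- qr(X[obs, , drop = FALSE])
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- X[obs, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, y[obs])
  n <- sum(obs); p <- ncol(Xo)
  df <- max(n - p, 1)
  s2 <- sum(fit$residuals^2) / df
  sigma2 <- s2 * df / stats::rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, p)))
  beta <- MASS::mvrnorm(1, fit$coefficients, sigma2 * XtXinv)
  mu <- drop(X[!obs, keep, drop = FALSE] %*% beta)
  mu + stats::rnorm(sum(!obs), 0, sqrt(sigma2))
}

draw_binary <- function(y, X, levels) {
  obs <- !is.na(y)
  yy <- as.integer(y[obs] == levels[2])
  fit <- suppressWarnings(
    stats::glm.fit(X[obs, , drop = FALSE], yy,
                   family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  V <- tryCatch({
    w <- fit$weights
    chol2inv(chol(crossprod(X[obs, , drop = FALSE] * sqrt(w)) + diag(1e-8, ncol(X))))
  }, error = function(e) diag(1e-6, ncol(X)))
  beta <- MASS::mvrnorm(1, co, V)
  pr <- stats::plogis(drop(X[!obs, , drop = FALSE] %*% beta))
  levels[1 + stats::rbinom(sum(!obs), 1, pr)]
}

draw_multinomial <- function(y, X, levels) {
  obs <- !is.na(y)
  Xp <- X[, -1, drop = FALSE]
  colnames(Xp) <- paste0("p", seq_len(ncol(Xp)))
  dat <- cbind(data.frame(y = factor(y[obs], levels = levels)),
               as.data.frame(Xp[obs, , drop = FALSE]))
  fit <- nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 200)
  nd <- as.data.frame(Xp[!obs, , drop = FALSE])
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) {
    pr <- if (sum(!obs) == 1) matrix(pr, nrow = 1) else
      cbind(1 - pr, pr) # two-level fallback
  }
  apply(pr, 1, function(p) sample(levels, 1, prob = p))
}

#' Multiply impute missing covariates by chained equations
#'
#' @param data Data frame; character columns are treated as factors.
#' @param vars Covariates to impute. Defaults to every column with missing
#'   values that is not protected.
#' @param protected Analysis variables that must be complete (exposures,
#'   outcomes); missingness in them raises a protection error.
#' @param m Number of completed datasets (the conventional default here
#'   is 30).
#' @param iterations Chained-equation sweeps per dataset.
#' @param seed Master seed; per-imputation sub-seeds are derived from it
#'   deterministically, so identical seed and configuration reproduce
#'   identical imputations.
#' @param exclude Columns excluded from the predictor set (identifiers).
#' @return Object of class `imputation_run`: list with `completed` (list of
#'   m data frames), `vars`, `m`, `iterations`, `seed`.
#' @export
impute_covariates <- function(data, vars = NULL, protected = character(0),
                              m = 30, iterations = 10, seed = NULL,
                              exclude = "subject_id") {
  if (m < 2) stop_ec("insufficient_imputations", "m must be at least 2")
  bad <- protected[vapply(protected, function(v) anyNA(data[[v]]), logical(1))]
  if (length(bad)) {
    stop_ec("protection_error",
            "protected variable(s) contain missing values: %s",
            paste(bad, collapse = ", "))
  }
  pool_cols <- setdiff(names(data), exclude)
  if (is.null(vars)) {
    vars <- setdiff(pool_cols[vapply(pool_cols, function(v) anyNA(data[[v]]),
                                     logical(1))],
                    protected)
  }
  stray <- setdiff(vars, names(data))
  if (length(stray)) {
    stop_ec("configuration_error", "unknown variable(s): %s",
            paste(stray, collapse = ", "))
  }
  frac <- vapply(vars, function(v) mean(is.na(data[[v]])), numeric(1))
  if (any(frac >= 0.9)) {
    stop_ec("validation_error", "variable(s) over 90%% missing: %s",
            paste(vars[frac >= 0.9], collapse = ", "))
  }
  other_miss <- setdiff(pool_cols[vapply(pool_cols, function(v) anyNA(data[[v]]),
                                         logical(1))],
                        vars)
  if (length(other_miss)) {
    stop_ec("validation_error",
            "missingness outside the declared imputation variables: %s",
            paste(other_miss, collapse = ", "))
  }
  work <- data
  for (v in names(work)) {
    if (is.character(work[[v]])) work[[v]] <- factor(work[[v]])
  }
  if (!length(vars) || all(frac == 0)) {
    return(structure(list(completed = rep(list(data), m), vars = vars,
                          m = m, iterations = iterations, seed = seed),
                     class = "imputation_run"))
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, m)
  vars <- vars[order(frac[vars])]

  predictors_for <- function(d, target) {
    preds <- setdiff(pool_cols, target)
    stats::model.matrix(~ ., data = d[, preds, drop = FALSE])
  }

  completed <- lapply(seq_len(m), function(im) {
    set.seed(sub_seeds[im])
    d <- work
    # initialize missing entries by sampling observed values
    for (v in vars) {
      nas <- is.na(d[[v]])
      d[[v]][nas] <- sample(d[[v]][!nas], sum(nas), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in vars) {
        nas <- is.na(work[[v]])
        if (!any(nas)) next
        y <- d[[v]]
        y[nas] <- NA
        X <- predictors_for(d, v)
        if (is.numeric(work[[v]])) {
          d[[v]][nas] <- draw_continuous(y, X)
        } else {
          lv <- levels(work[[v]])
          d[[v]][nas] <- if (length(lv) == 2) {
            draw_binary(y, X, lv)
          } else {
            draw_multinomial(y, X, lv)
          }
        }
      }
    }
    # restore original column types (factors back to character if needed)
    for (v in names(d)) {
      if (is.character(data[[v]]) && is.factor(d[[v]])) {
        d[[v]] <- as.character(d[[v]])
      }
    }
    d
  })
  structure(list(completed = completed, vars = vars, m = m,
                 iterations = iterations, seed = seed),
            class = "imputation_run")
}

#' @export
print.imputation_run <- function(x, ...) {
  cat(sprintf("<imputation_run> m=%d datasets, %d iteration(s), imputed: %s\n",
              x$m, x$iterations,
              if (length(x$vars)) paste(x$vars, collapse = ", ") else "(nothing)"))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' \eqn{\bar{Q} = m^{-1}\sum Q_i}, within-variance \eqn{W = m^{-1}\sum U_i},
#' between-variance \eqn{B} the unbiased variance of the \eqn{Q_i}, total
#' \eqn{T = W + (1 + 1/m)B}; the CI and p-value use a t reference with
#' Barnard-Rubin small-sample degrees of freedom when a complete-data df is
#' supplied (the large-sample df \eqn{(m-1)/\lambda^2} otherwise).
#'
#' @param q Per-imputation estimates \eqn{Q_i}.
#' @param u Per-imputation squared standard errors \eqn{U_i}.
#' @param df_com Complete-data residual degrees of freedom (`Inf` for the
#'   large-sample form).
#' @return List of class `pooled_result`: `qbar`, `W`, `B`, `T`, `se`, `df`,
#'   `ci_lo`, `ci_hi`, `p`, `m`, `riv` (relative increase in variance).
#' @export
pool_rubin <- function(q, u, df_com = Inf) {
  m <- length(q)
  if (m < 2) stop_ec("insufficient_imputations", "need at least 2 imputations")
  if (length(u) != m) stop_ec("configuration_error", "q and u lengths differ")
  if (any(u <= 0)) stop_ec("validation_error", "all U_i must be positive")
  qbar <- mean(q)
  W <- mean(u)
  B <- stats::var(q)
  Tv <- W + (1 + 1 / m) * B
  riv <- (1 + 1 / m) * B / W
  lambda <- (1 + 1 / m) * B / Tv
  if (B == 0) {
    df <- df_com
  } else {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else {
      df_old
    }
  }
  se <- sqrt(Tv)
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  p <- if (is.finite(df)) 2 * stats::pt(-abs(qbar / se), df) else
    2 * stats::pnorm(-abs(qbar / se))
  structure(list(qbar = qbar, W = W, B = B, T = Tv, se = se, df = df,
                 ci_lo = qbar - tcrit * se, ci_hi = qbar + tcrit * se,
                 p = p, m = m, riv = riv),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result> Qbar=%.4g (95%% CI %.4g to %.4g), T=%.4g (W=%.4g, B=%.4g), df=%.1f, m=%d\n",
              x$qbar, x$ci_lo, x$ci_hi, x$T, x$W, x$B, x$df, x$m))
  invisible(x)
}

#' Fit an association on each imputed dataset and pool
#'
#' Runs [fit_association()] on every completed dataset and combines each
#' term's estimates with [pool_rubin()], using the complete-data residual df.
#'
#' @param datasets List of completed data frames (or an `imputation_run`).
#' @inheritParams fit_association
#' @return An `association_result` data frame with `pooled = TRUE`.
#' @export
fit_association_pooled <- function(datasets, outcome, exposure,
                                   covariates = character(0),
                                   reference = NULL, icv_adjust = FALSE,
                                   tier = NA_character_) {
  if (inherits(datasets, "imputation_run")) datasets <- datasets$completed
  fits <- lapply(datasets, fit_association, outcome = outcome,
                 exposure = exposure, covariates = covariates,
                 reference = reference, icv_adjust = icv_adjust, tier = tier)
  template <- fits[[1]]
  for (r in seq_len(nrow(template))) {
    if (is.na(template$estimate[r])) next # reference row
    q <- vapply(fits, function(f) f$estimate[r], numeric(1))
    u <- vapply(fits, function(f) f$se[r]^2, numeric(1))
    n <- template$n[r]
    k <- length(covariates) + 2 + icv_adjust
    pl <- pool_rubin(q, u, df_com = n - k)
    template$estimate[r] <- pl$qbar
    template$se[r] <- pl$se
    template$ci_lo[r] <- pl$ci_lo
    template$ci_hi[r] <- pl$ci_hi
    template$p[r] <- pl$p
  }
  template$pooled <- TRUE
  template
}
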