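# Conditional growth variables: the weight SD score at each occasion is
# regressed on the scores at all earlier occasions and the residual kept,
# giving growth variables that are uncorrelated with all prior size --
# "growth in that window independent of growth before it". Residuals are
# standardized to SD 1 so association coefficients read "per 1 SD-score-unit
# of conditional growth". Fitting is complete-case: subjects missing any
# occasion are excluded and counted, mirroring the much smaller analysis n
# of conditional analyses in real cohorts.

#' Fit conditional growth variables by sequential residualization
#'
#' For occasion \eqn{k \ge 2}, ordinary least squares of \eqn{z_k} on
#' \eqn{z_1, \ldots, z_{k-1}} with intercept; the residual, divided by its
#' sample SD, is the conditional growth variable. The first occasion's
#' conditional variable is its standardized score.
#'
#' @param wide Wide per-subject table containing the score columns.
#' @param occasions Ordered character vector of score column names
#'   (chronological order; the order is fixed by the schedule, never inferred
#'   from the data).
#' @param id_col Name of the subject identifier column, if present.
#' @return A `conditional_growth_set` with elements `coefficients` (named
#'   list per occasion: intercept + slopes on earlier occasions), `scale`
#'   (residual SDs), `centers` (first-occasion mean), `residuals` (data frame
#'   of `cond_*` columns for the fitting subjects), `analysis_ids`,
#'   `n_input`, `n_complete`, and `degenerate` flags.
#' @export
fit_conditional_set <- function(wide,
                                occasions = c("z_t2", "z_t3", "z_birth",
                                              "z_m6", "z_m12", "z_m24"),
                                id_col = "subject_id") {
  if (length(occasions) < 2) {
    stop_ec("configuration_error", "need at least 2 occasions")
  }
  miss <- setdiff(occasions, names(wide))
  if (length(miss)) {
    stop_ec("schema_error", "missing score column(s): %s",
            paste(miss, collapse = ", "))
  }
  Z <- as.matrix(wide[, occasions, drop = FALSE])
  cc <- stats::complete.cases(Z)
  n <- sum(cc)
  if (n < 10 * length(occasions)) {
    stop_ec("insufficient_data",
            "only %d complete-case subjects for %d occasions (need >= %d)",
            n, length(occasions), 10 * length(occasions))
  }
  Z <- Z[cc, , drop = FALSE]

  coefs <- vector("list", length(occasions))
  names(coefs) <- occasions
  scl <- numeric(length(occasions))
  names(scl) <- occasions
  degen <- logical(length(occasions))
  names(degen) <- occasions
  resid <- matrix(NA_real_, n, length(occasions))

  mu1 <- mean(Z[, 1])
  s1 <- stats::sd(Z[, 1])
  if (s1 < 1e-12) {
    degen[1] <- TRUE
    s1 <- 1
  }
  coefs[[1]] <- c(`(Intercept)` = mu1)
  scl[1] <- s1
  resid[, 1] <- (Z[, 1] - mu1) / s1

  for (k in seq_along(occasions)[-1]) {
    X <- cbind(1, Z[, seq_len(k - 1), drop = FALSE])
    colnames(X) <- c("(Intercept)", occasions[seq_len(k - 1)])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
      stop_ec("collinearity_error",
              "earlier occasion scores are collinear at '%s' (involving: %s)",
              occasions[k], paste(dropped, collapse = ", "))
    }
    beta <- qr.coef(qrX, Z[, k])
    r <- Z[, k] - drop(X %*% beta)
    s <- stats::sd(r)
    if (s < 1e-10) {
      degen[k] <- TRUE
      s <- 1
    }
    names(beta) <- colnames(X)
    coefs[[k]] <- beta
    scl[k] <- s
    resid[, k] <- r / s
  }

  rd <- as.data.frame(resid)
  names(rd) <- paste0("cond_", occasions)
  ids <- if (id_col %in% names(wide)) wide[[id_col]][cc] else which(cc)
  structure(list(occasions = occasions, coefficients = coefs, scale = scl,
                 residuals = rd, analysis_ids = ids,
                 n_input = nrow(wide), n_complete = n, degenerate = degen),
            class = "conditional_growth_set")
}

#' @export
print.conditional_growth_set <- function(x, ...) {
  cat(sprintf("<conditional_growth_set> %d occasions, fitted on %d/%d subjects\n",
              length(x$occasions), x$n_complete, x$n_input))
  if (any(x$degenerate)) {
    cat("  degenerate (zero-variance) residual(s):",
        paste(x$occasions[x$degenerate], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a fitted conditional growth set to new subjects
#'
#' Residuals are computed from the stored regression coefficients and stored
#' residual scaling, without refitting. Columns are matched by name, so
#' column order in `new_wide` is irrelevant.
#'
#' @param set A `conditional_growth_set`.
#' @param new_wide Wide table containing all occasion score columns.
#' @return Data frame of `cond_*` columns, one row per row of `new_wide`
#'   (rows with missing earlier scores give `NA`).
#' @export
apply_conditional_set <- function(set, new_wide) {
  stopifnot(inherits(set, "conditional_growth_set"))
  miss <- setdiff(set$occasions, names(new_wide))
  if (length(miss)) {
    stop_ec("schema_error", "new data lacks occasion column(s): %s",
            paste(miss, collapse = ", "))
  }
  Z <- as.matrix(new_wide[, set$occasions, drop = FALSE])
  out <- matrix(NA_real_, nrow(Z), length(set$occasions))
  out[, 1] <- (Z[, 1] - set$coefficients[[1]][["(Intercept)"]]) / set$scale[1]
  for (k in seq_along(set$occasions)[-1]) {
    X <- cbind(1, Z[, seq_len(k - 1), drop = FALSE])
    r <- Z[, k] - drop(X %*% set$coefficients[[k]])
    out[, k] <- r / set$scale[k]
  }
  rd <- as.data.frame(out)
  names(rd) <- paste0("cond_", set$occasions)
  rd
}
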