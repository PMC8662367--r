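# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Occasion labels in chronological order
#'
#' The fixed measurement schedule: second and third trimester, birth, and the
#' 6-, 12- and 24-month infant visits, plus the childhood follow-up visit.
#' Occasion order is always this enumerated list, never inferred from ages.
#'
#' @return Character vector of occasion labels.
#' @export
occasion_levels <- function() {
  c("T2", "T3", "birth", "m6", "m12", "m24", "childhood")
}

stop_ec <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "earlygrowth_error")))
}

assert_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) {
    stop_ec("invalid_measurement", "`%s` must be numeric", name)
  }
  if (finite && any(!is.finite(x[!is.na(x)]))) {
    stop_ec("invalid_measurement", "`%s` contains non-finite values", name)
  }
  if (positive && any(x[!is.na(x)] <= 0)) {
    stop_ec("invalid_measurement", "`%s` must be strictly positive", name)
  }
  invisible(x)
}

#' Validate a long-format growth table
#'
#' Checks the contract of the long measurement table: one row per
#' subject-by-occasion, positive ages and weights, known occasion labels.
#'
#' @param data Data frame with columns `subject_id`, `sex`, `occasion`,
#'   `age`, `weight` (fetal occasions in grams and gestational weeks, infant
#'   occasions in kilograms and postnatal months).
#' @return The input, invisibly, with `occasion` as a factor in schedule order.
#' @export
validate_growth_long <- function(data) {
  need <- c("subject_id", "sex", "occasion", "age", "weight")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ec("schema_error", "long table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(as.character(data$occasion)), occasion_levels())
  if (length(bad)) {
    stop_ec("schema_error", "unknown occasion label(s): %s",
            paste(bad, collapse = ", "))
  }
  ok <- !is.na(data$age)
  if (any(data$age[ok] <= 0)) {
    stop_ec("invalid_measurement", "ages must be strictly positive")
  }
  ok <- !is.na(data$weight)
  if (any(data$weight[ok] <= 0)) {
    stop_ec("invalid_measurement", "weights must be strictly positive")
  }
  key <- paste(data$subject_id, data$occasion)
  if (anyDuplicated(key)) {
    stop_ec("schema_error", "duplicated (subject_id, occasion) rows")
  }
  data$occasion <- factor(as.character(data$occasion), levels = occasion_levels())
  invisible(data)
}

# Natural (restricted) cubic spline basis with interior knots at quantiles;
# returns the basis and the knot placement so it can be re-evaluated later.
ns_quantile_basis <- function(x, n_knots = 4) {
  probs <- seq_len(n_knots) / (n_knots + 1)
  knots <- unique(stats::quantile(x, probs = probs, names = FALSE, type = 7))
  bk <- range(x)
  list(basis = splines::ns(x, knots = knots, Boundary.knots = bk),
       knots = knots, boundary = bk)
}

# FNV-1a 32-bit hash of a character scalar; used for config manifests.
# Arithmetic stays on doubles below 2^53: the xor touches only the low byte
# and the 32-bit modular multiply is done in 16-bit halves.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(paste(txt, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * m + (hi * m %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
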