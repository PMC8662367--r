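#' Hadlock fetal weight coefficients
#'
#' The three-parameter (head circumference, abdominal circumference, femur
#' length) estimated-fetal-weight model
#' \deqn{\log_{10} EFW = c_0 + c_1\,AC\cdot FL + c_2\,HC + c_3\,AC + c_4\,FL}
#' with circumferences and femur length in centimeters and EFW in grams.
#' Coefficients are version-stamped so alternative variants of the formula
#' can be swapped in.
#'
#' @param version Coefficient set identifier. Only `"hadlock3-1985"`, the
#'   widely used HC/AC/FL model, is bundled.
#' @return A list with elements `c0`..`c4` and `version`.
#' @export
hadlock_coefficients <- function(version = "hadlock3-1985") {
  sets <- list(
    "hadlock3-1985" = list(c0 = 1.326, c1 = -0.00326, c2 = 0.0107,
                           c3 = 0.0438, c4 = 0.158)
  )
  if (!version %in% names(sets)) {
    stop_ec("configuration_error", "unknown Hadlock coefficient version '%s'",
            version)
  }
  c(sets[[version]], list(version = version))
}

#' Estimate fetal weight from ultrasound biometry
#'
#' Applies the Hadlock HC/AC/FL formula (see [hadlock_coefficients()]).
#' Vectorized over the biometry arguments.
#'
#' @param hc Head circumference, cm.
#' @param ac Abdominal circumference, cm.
#' @param fl Femur length, cm.
#' @param coefficients Coefficient record as returned by
#'   [hadlock_coefficients()].
#' @return Estimated fetal weight in grams.
#' @export
#' @examples
#' estimate_fetal_weight(20, 16, 3) # second-trimester scale, ~362 g
estimate_fetal_weight <- function(hc, ac, fl,
                                  coefficients = hadlock_coefficients()) {
  need <- c("c0", "c1", "c2", "c3", "c4")
  miss <- setdiff(need, names(coefficients))
  if (length(miss)) {
    stop_ec("configuration_error", "missing Hadlock coefficient(s): %s",
            paste(miss, collapse = ", "))
  }
  assert_numeric(hc, "hc", positive = TRUE)
  assert_numeric(ac, "ac", positive = TRUE)
  assert_numeric(fl, "fl", positive = TRUE)
  k <- coefficients
  10^(k$c0 + k$c1 * ac * fl + k$c2 * hc + k$c3 * ac + k$c4 * fl)
}
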