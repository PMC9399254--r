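# Quantitative bias analysis: E-values for unmeasured confounding.

#' E-value for a rate ratio and its confidence interval
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need to have with both the
#' treatment and the outcome, conditional on measured covariates, to
#' fully explain away an observed ratio (VanderWeele-Ding). For RR* =
#' max(rr, 1/rr), E = RR* + sqrt(RR* (RR* - 1)). Rate ratios are treated
#' directly on the risk-ratio scale. The confidence-limit E-value uses
#' the limit closer to the null and equals 1 when the interval crosses 1.
#'
#' @param rr observed ratio (> 0).
#' @param ci_low,ci_high optional confidence limits with
#'   `ci_low <= rr <= ci_high`.
#' @return object of class `evalue_result`: list with rr, ci_low,
#'   ci_high, e_point, e_ci (NA when no CI was supplied).
#' @export
e_value <- function(rr, ci_low = NA, ci_high = NA) {
  if (!is.numeric(rr) || is.na(rr) || rr <= 0) {
    stop("rr must be a positive number", call. = FALSE)
  }
  have_ci <- !is.na(ci_low) && !is.na(ci_high)
  if (have_ci) {
    if (ci_low <= 0 || ci_high <= 0) stop("confidence limits must be positive",
                                          call. = FALSE)
    if (ci_low > rr || ci_high < rr) {
      stop("confidence interval must contain the point estimate",
           call. = FALSE)
    }
  }
  ev <- function(r) {
    rs <- max(r, 1 / r)
    rs + sqrt(rs * (rs - 1))
  }
  e_ci <- NA_real_
  if (have_ci) {
    e_ci <- if (ci_low <= 1 && ci_high >= 1) {
      1
    } else if (rr > 1) ev(ci_low) else ev(ci_high)
  }
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 e_point = ev(rr), e_ci = e_ci),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, digits = 2, ...) {
  cat(sprintf("E-value: %.*f (point estimate RR = %.*f)\n", digits,
              x$e_point, digits, x$rr))
  if (!is.na(x$e_ci)) {
    cat(sprintf("E-value for the CI limit closer to the null: %.*f\n",
                digits, x$e_ci))
  }
  invisible(x)
}
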