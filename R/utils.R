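#' @keywords internal
#' @importFrom survival Surv strata coxph
#' @importFrom MASS glm.nb
#' @importFrom stats glm
"_PACKAGE"

# Risk-window labels, in display order. Reference stratum is `in_gt4`
# (more than four weeks into a treatment episode).
WINDOW_LEVELS <- c("in_1_4", "in_gt4", "out_1_4", "out_gt4")

DRUG_LEVELS <- c("methadone", "buprenorphine")

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

AGE_BAND_BREAKS <- c(18, 25, 35, 45)
AGE_BAND_LABELS <- c("18-24", "25-34", "35-44", "45-64")

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' Assign an age band given age in whole years
#'
#' Bands follow the conventional OAT-cohort grouping 18-24, 25-34, 35-44,
#' 45-64. Ages above 64 (attained during follow-up) stay in the top band.
#' @param age integer vector of ages in years.
#' @return factor with levels `18-24`, `25-34`, `35-44`, `45-64`.
#' @keywords internal
age_band <- function(age) {
  cut(age, breaks = c(AGE_BAND_BREAKS, Inf), labels = AGE_BAND_LABELS,
      right = FALSE)
}

# Age in whole years at date `d` for a birth date taken as Jan 1 of
# `birth_year` (inputs carry birth year only).
age_at <- function(d, birth_year) {
  as.integer(format(as_date(d), "%Y")) - as.integer(birth_year)
}
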