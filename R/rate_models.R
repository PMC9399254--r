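# Rate-ratio and hazard-ratio estimation for person-time data.
#
# Crude rate ratios come from closed-form stratum arithmetic; model-based
# estimates come from Poisson or NB2 negative-binomial regression with a
# log person-time offset (multiple events per patient) and from Cox
# proportional-hazards models on counting-process intervals (first
# events). Weighted fits always pair with a cluster-robust sandwich
# covariance by patient.

#' Crude rate ratio from stratum counts
#'
#' RR = (events1 / py1) / (events0 / py0), with a log-normal 95% CI using
#' SE(log RR) = sqrt(1/events1 + 1/events0). With zero events in either
#' cell the point estimate may be 0 or infinite and the CI is undefined
#' (returned as NA with a note).
#'
#' @param events1,py1 event count and person-time in the index stratum.
#' @param events0,py0 event count and person-time in the reference
#'   stratum.
#' @param conf_level confidence level, default 0.95.
#' @return object of class `rate_ratio_estimate`: list with estimate,
#'   conf_low, conf_high, se_log, flavour (`"crude"`), and the inputs.
#' @export
crude_rate_ratio <- function(events1, py1, events0, py0,
                             conf_level = 0.95) {
  if (py1 <= 0 || py0 <= 0) stop("person-time must be positive",
                                 call. = FALSE)
  if (events1 < 0 || events0 < 0) stop("event counts must be non-negative",
                                       call. = FALSE)
  rr <- (events1 / py1) / (events0 / py0)
  if (events1 == 0 || events0 == 0) {
    res <- list(estimate = rr, conf_low = NA_real_, conf_high = NA_real_,
                se_log = NA_real_, flavour = "crude",
                note = "zero events in a cell; CI undefined")
  } else {
    se <- sqrt(1 / events1 + 1 / events0)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    res <- list(estimate = rr, conf_low = rr * exp(-z * se),
                conf_high = rr * exp(z * se), se_log = se,
                flavour = "crude", note = NULL)
  }
  res$inputs <- c(events1 = events1, py1 = py1, events0 = events0,
                  py0 = py0)
  structure(res, class = "rate_ratio_estimate")
}

#' @export
print.rate_ratio_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s rate ratio: %.*f (%.*f-%.*f)\n", x$flavour, digits,
              x$estimate, digits, x$conf_low, digits, x$conf_high))
  invisible(x)
}

check_records <- function(records) {
  assert_columns(records, c("events", "py"), "count records")
  if (any(records$py <= 0)) stop("person-time must be positive",
                                 call. = FALSE)
  if (any(records$events < 0)) stop("events must be non-negative",
                                    call. = FALSE)
  invisible(records)
}

#' Fit a Poisson rate model with person-time offset
#'
#' Log-link Poisson regression of event counts on the given terms with
#' offset log(person-time); exponentiated coefficients are rate ratios.
#' Weighted fits (non-integer pseudo-counts under IPW) are legitimate
#' estimating-equation fits, so the usual non-integer warning is
#' suppressed; use [robust_variance()] for their covariance.
#'
#' @param records data frame with columns `events`, `py` and the model
#'   covariates.
#' @param terms character vector of right-hand-side terms, e.g.
#'   `c("window", "drug")`.
#' @param weights optional per-record weights.
#' @return the fitted `glm` object.
#' @export
fit_poisson <- function(records, terms, weights = NULL) {
  check_records(records)
  dat <- records
  dat$.w <- weights %||% rep(1, nrow(dat))
  f <- stats::as.formula(paste("events ~", paste(terms, collapse = " + "),
                               "+ offset(log(py))"))
  fit <- withCallingHandlers(
    stats::glm(f, data = dat, family = stats::poisson(), weights = .w),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("Poisson fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  if (anyNA(stats::coef(fit))) {
    warning("rank-deficient design: coefficient(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  fit
}

#' Fit an NB2 negative-binomial rate model with person-time offset
#'
#' Mean mu, variance mu + alpha * mu^2 (alpha = 1/theta in the
#' `MASS::glm.nb` parameterisation), maximum likelihood with offset
#' log(person-time). As alpha approaches 0 the fit reduces to Poisson.
#'
#' @inheritParams fit_poisson
#' @return the fitted `negbin` object, with the dispersion available as
#'   `alpha(fit) = 1/fit$theta`.
#' @export
fit_negbin <- function(records, terms, weights = NULL) {
  check_records(records)
  dat <- records
  dat$.w <- weights %||% rep(1, nrow(dat))
  f <- stats::as.formula(paste("events ~", paste(terms, collapse = " + "),
                               "+ offset(log(py))"))
  # warm-start from the Poisson fit: same mean structure, and a moment
  # estimate of the dispersion, which cuts the alternating iterations
  pois <- fit_poisson(records, terms, weights)
  mu <- stats::fitted(pois)
  y <- dat$events
  alpha0 <- sum(dat$.w * ((y - mu)^2 - mu)) / sum(dat$.w * mu^2)
  theta0 <- 1 / min(max(alpha0, 1e-3), 100)
  b0 <- stats::coef(pois)
  fit <- tryCatch({
    if (anyNA(b0)) {
      suppressWarnings(MASS::glm.nb(f, data = dat, weights = .w,
                                    maxit = 50))
    } else {
      suppressWarnings(MASS::glm.nb(f, data = dat, weights = .w,
                                    maxit = 50, init.theta = theta0,
                                    start = b0))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # theta.ml diverges when the data are equi- or under-dispersed; the
    # Poisson-limit fit with an essentially infinite, fixed theta is the
    # ML solution on the boundary
    theta_cap <- 1e7
    fit <- suppressWarnings(
      stats::glm(f, data = dat, weights = .w,
                 family = MASS::negative.binomial(theta = theta_cap)))
    fit$theta <- theta_cap
    fit$SE.theta <- NA_real_
    fit$twologlik <- 2 * as.numeric(stats::logLik(fit))
    class(fit) <- c("negbin", class(fit))
  }
  if (!fit$converged) {
    stop("negative binomial fit did not converge", call. = FALSE)
  }
  fit
}

#' Likelihood-ratio test for overdispersion
#'
#' Tests NB2 dispersion alpha = 0 (Poisson) against alpha > 0 by the
#' likelihood ratio between the negative-binomial and Poisson fits. The
#' null distribution is the boundary-corrected 50:50 mixture of a point
#' mass at zero and chi-squared with 1 df, so p = 0.5 * P(chi2_1 >=
#' statistic) when the statistic is positive. With no events the test is
#' undefined and the Poisson decision is returned.
#'
#' @inheritParams fit_poisson
#' @param alpha_level decision level, default 0.05.
#' @return list with statistic, p_value, overdispersed (logical) and
#'   family (`"negbin"` or `"poisson"`).
#' @export
overdispersion_test <- function(records, terms, weights = NULL,
                                alpha_level = 0.05) {
  check_records(records)
  if (sum(records$events) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                overdispersed = FALSE, family = "poisson"))
  }
  pois <- fit_poisson(records, terms, weights)
  nb <- tryCatch(fit_negbin(records, terms, weights),
                 error = function(e) NULL)
  if (is.null(nb)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                overdispersed = FALSE, family = "poisson"))
  }
  stat <- max(0, 2 * (as.numeric(stats::logLik(nb)) -
                        as.numeric(stats::logLik(pois))))
  p <- if (stat > 0) 0.5 * stats::pchisq(stat, df = 1,
                                         lower.tail = FALSE) else 1
  over <- p < alpha_level
  list(statistic = stat, p_value = p, overdispersed = over,
       family = if (over) "negbin" else "poisson")
}

#' Cluster-robust sandwich covariance
#'
#' Sandwich covariance clustered by patient, valid under
#' inverse-probability weighting and within-patient correlation of
#' repeated records; used for all weighted estimates.
#'
#' @param model a fitted `glm`/`negbin`/`coxph` model.
#' @param cluster vector of cluster identifiers (patient ids), aligned
#'   with the model frame rows.
#' @return covariance matrix of the coefficients.
#' @export
robust_variance <- function(model, cluster) {
  if (length(unique(cluster)) < 2L) {
    stop("at least two clusters are required", call. = FALSE)
  }
  sandwich::vcovCL(model, cluster = cluster)
}

#' Rate ratios (or hazard ratios) from a fitted model
#'
#' Exponentiates the model coefficients with Wald confidence intervals,
#' optionally under a supplied (e.g. cluster-robust) covariance.
#'
#' @param fit fitted `glm`, `negbin` or `coxph` model.
#' @param vcov optional covariance matrix, default the model-based one.
#' @param conf_level confidence level, default 0.95.
#' @param drop_intercept omit the intercept row (default TRUE).
#' @return data frame with term, estimate, conf_low, conf_high, se_log.
#' @export
rate_ratios <- function(fit, vcov = NULL, conf_level = 0.95,
                        drop_intercept = TRUE) {
  b <- stats::coef(fit)
  keep <- !is.na(b)
  V <- vcov %||% stats::vcov(fit)
  se <- sqrt(diag(V))[names(b)[keep]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = names(b)[keep], estimate = exp(b[keep]),
                    conf_low = exp(b[keep] - z * se),
                    conf_high = exp(b[keep] + z * se),
                    se_log = se, stringsAsFactors = FALSE)
  if (drop_intercept) out <- out[out$term != "(Intercept)", , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Cox proportional-hazards model for first overdose events
#'
#' Partial-likelihood fit (Breslow ties) on counting-process records
#' encoding time-varying exposure, with time measured in days since
#' index. Patients are censored at their first event, so each patient
#' carries at most one event. Weighted fits use the stabilised IPWs with
#' cluster-robust standard errors by patient.
#'
#' @param records first-event interval records with columns patient_id,
#'   tstart, tstop, event, plus covariates.
#' @param covariates character vector of model terms (e.g. `"drug"`,
#'   `"window"`).
#' @param weights optional per-record weights.
#' @param strata optional column name to stratify the baseline hazard by
#'   (e.g. follow-up-duration bands).
#' @return the fitted `coxph` object.
#' @export
fit_cox_first_event <- function(records, covariates, weights = NULL,
                                strata = NULL) {
  assert_columns(records, c("patient_id", "tstart", "tstop", "event"),
                 "cox records")
  if (sum(records$event) == 0) stop("no events; cannot fit Cox model",
                                    call. = FALSE)
  rhs <- paste(covariates, collapse = " + ")
  if (!is.null(strata)) rhs <- paste(rhs, sprintf("strata(%s)", strata),
                                     sep = " + ")
  f <- stats::as.formula(paste(
    "survival::Surv(tstart, tstop, event) ~", rhs))
  dat <- records
  dat$.w <- weights %||% rep(1, nrow(dat))
  fit <- survival::coxph(f, data = dat, weights = .w, ties = "breslow",
                         cluster = patient_id, x = FALSE, y = FALSE)
  if (!is.null(fit$info) && isTRUE(grepl("did not converge", fit$info))) {
    stop("Cox model did not converge", call. = FALSE)
  }
  fit
}
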