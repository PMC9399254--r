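# Propensity-score estimation, stabilised inverse-probability-of-
# treatment weights, and covariate-balance diagnostics for the
# methadone-vs-buprenorphine comparison.

#' Fit a propensity model for treatment modality
#'
#' Main-effects logistic regression of receiving methadone (vs
#' buprenorphine) on the supplied baseline covariates, fitted by maximum
#' likelihood. The fitted probabilities P(methadone | X) are the
#' propensity scores.
#'
#' @param data one row per patient; must contain the treatment column and
#'   every covariate. Character covariates are treated as factors.
#' @param covariates character vector of covariate column names.
#' @param treatment treatment column name, default `"drug"`, with values
#'   `"methadone"` / `"buprenorphine"`.
#' @return object of class `oat_propensity`: list with `model` (the glm),
#'   `scores` (P(methadone | X) per row of `data`) and `treatment`.
#' @export
fit_propensity <- function(data, covariates, treatment = "drug") {
  assert_columns(data, c(treatment, covariates), "covariate data")
  tr <- data[[treatment]]
  if (length(unique(tr)) < 2L || min(table(tr)) < 2L) {
    stop("need at least two patients per modality", call. = FALSE)
  }
  df <- data[covariates]
  for (v in covariates) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  df$.oat_y <- as.integer(tr == "methadone")
  f <- stats::reformulate(covariates, response = ".oat_y")
  fit <- stats::glm(f, data = df, family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps)) {
    stop("propensity scores numerically 0 or 1 (complete or ",
         "quasi-complete separation); consider collapsing sparse ",
         "covariate categories", call. = FALSE)
  }
  structure(list(model = fit, scores = as.numeric(p),
                 treatment = treatment), class = "oat_propensity")
}

#' Stabilised inverse-probability-of-treatment weights
#'
#' For propensity score p = P(methadone | X) and marginal methadone
#' probability p_m, methadone recipients receive weight p_m / p and
#' buprenorphine recipients (1 - p_m) / (1 - p). Stabilised weights have
#' mean approximately 1 and leave the pseudo-population size near the
#' sample size.
#'
#' @param scores propensity scores in (0, 1), e.g. from
#'   [fit_propensity()] (an `oat_propensity` object is also accepted).
#' @param modality character vector, `"methadone"` /
#'   `"buprenorphine"`, aligned with `scores`.
#' @param truncate_quantiles optional length-2 probabilities (e.g.
#'   `c(0.01, 0.99)`) at which the weights are winsorised; `NULL`
#'   (default) applies no truncation.
#' @return numeric vector of positive, finite weights.
#' @export
stabilised_ipw <- function(scores, modality, truncate_quantiles = NULL) {
  if (inherits(scores, "oat_propensity")) scores <- scores$scores
  if (any(scores <= 0 | scores >= 1)) {
    stop("propensity scores must lie strictly within (0, 1); ",
         "enable truncation or refit the model", call. = FALSE)
  }
  is_meth <- modality == "methadone"
  p_marg <- mean(is_meth)
  w <- ifelse(is_meth, p_marg / scores, (1 - p_marg) / (1 - scores))
  if (!is.null(truncate_quantiles)) {
    q <- stats::quantile(w, truncate_quantiles, names = FALSE)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  w
}

#' Standardised differences of baseline covariates between modalities
#'
#' For each covariate (categorical covariates are expanded to one
#' indicator per level) the standardised difference between methadone
#' and buprenorphine recipients is (p1 - p2) / sqrt((v1 + v2) / 2),
#' where p and v are the (optionally weighted) group means and
#' variances; for an indicator v = p (1 - p). The sign convention is
#' methadone minus buprenorphine. A covariate with zero variance in both
#' groups has standardised difference 0.
#'
#' @param data one row per patient with treatment and covariate columns.
#' @param covariates covariate column names.
#' @param treatment treatment column, default `"drug"`.
#' @param weights optional per-patient weights (e.g. stabilised IPWs);
#'   `NULL` for the unweighted differences.
#' @return data frame with columns covariate, level, mean_methadone,
#'   mean_buprenorphine, std_diff.
#' @export
standardised_differences <- function(data, covariates, treatment = "drug",
                                     weights = NULL) {
  assert_columns(data, c(treatment, covariates), "covariate data")
  w <- weights %||% rep(1, nrow(data))
  g1 <- data[[treatment]] == "methadone"

  wmean <- function(x, sel) sum(w[sel] * x[sel]) / sum(w[sel])
  wvar <- function(x, sel) {
    m <- wmean(x, sel)
    sum(w[sel] * (x[sel] - m)^2) / sum(w[sel])
  }

  rows <- list()
  for (v in covariates) {
    x <- data[[v]]
    if (is.numeric(x) && !is.integer(x) && length(unique(x)) > 2L) {
      m1 <- wmean(x, g1); m2 <- wmean(x, !g1)
      pooled <- (wvar(x, g1) + wvar(x, !g1)) / 2
      sd_ <- if (pooled > 0) (m1 - m2) / sqrt(pooled) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(covariate = v, level = NA_character_,
                   mean_methadone = m1, mean_buprenorphine = m2,
                   std_diff = sd_, stringsAsFactors = FALSE)
    } else {
      lv <- if (is.logical(x) || (is.numeric(x) &&
                                  all(x %in% c(0, 1)))) {
        list(vals = list(x == 1 | x == TRUE), labs = "yes")
      } else {
        xl <- as.character(x)
        labs <- sort(unique(xl))
        list(vals = lapply(labs, function(l) xl == l), labs = labs)
      }
      for (i in seq_along(lv$labs)) {
        ind <- as.numeric(lv$vals[[i]])
        p1 <- wmean(ind, g1); p2 <- wmean(ind, !g1)
        pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
        sd_ <- if (pooled > 0) (p1 - p2) / sqrt(pooled) else 0
        rows[[length(rows) + 1L]] <-
          data.frame(covariate = v, level = lv$labs[i],
                     mean_methadone = p1, mean_buprenorphine = p2,
                     std_diff = sd_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
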