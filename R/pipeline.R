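# End-to-end orchestration: clean -> switch-censor -> episodes ->
# person-time -> ascertainment -> weighting -> models -> bias analysis,
# with an audit trail and deterministic, optionally file-based outputs.

#' Built-in example code lists
#'
#' A small illustrative code list covering non-fatal overdose (ICD-10
#' T40* poisoning plus T43.6), ONS-style drug-poisoning death codes
#' (X40-X44), overdose history, and analgesia-formulation product
#' exclusions matching the synthetic generator's product codes. Real
#' analyses should substitute locally governed lists via
#' [read_code_list()].
#'
#' @return a [code_list()].
#' @export
oat_default_code_lists <- function() {
  read_code_list(system.file("extdata", "default_code_lists.csv",
                             package = "oatrisk", mustWork = TRUE))
}

#' Published stratum counts from a large English OAT cohort
#'
#' Person-years and non-fatal overdose counts per treatment status,
#' risk window and modality, as reported by a nationwide primary-care
#' cohort of opioid agonist treatment recipients (1998-2017), for both
#' the multiple-event (`event_rate`) and first-event (`incidence`)
#' analyses. Useful for crude rate-ratio arithmetic and as a
#' plausibility reference for synthetic cohorts.
#'
#' @return data frame with columns measure, stratum, group,
#'   person_years, events.
#' @export
oat_reference_counts <- function() {
  utils::read.csv(system.file("extdata", "reference_stratum_counts.csv",
                              package = "oatrisk", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published cohort totals and headline weighted estimates
#'
#' Scalar summaries from the same cohort as [oat_reference_counts()]:
#' cohort size, total person-years, admission and patient counts, and
#' the weighted buprenorphine-vs-methadone rate ratio with its 95% CI
#' (inputs to E-value bias analysis).
#'
#' @return named numeric vector.
#' @export
oat_reference_totals <- function() {
  df <- utils::read.csv(system.file("extdata", "reference_totals.csv",
                                    package = "oatrisk", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

resolve_family <- function(records, terms, model_family, weights = NULL) {
  if (model_family != "auto") return(model_family)
  overdispersion_test(records, terms, weights)$family
}

fit_rate <- function(records, terms, family, weights = NULL) {
  if (family == "negbin") fit_negbin(records, terms, weights)
  else fit_poisson(records, terms, weights)
}

# exponentiated coefficients for the requested terms under model-based
# or cluster-robust variance, labelled with a flavour
flavoured_rrs <- function(fit, flavour, robust_cluster = NULL,
                          keep = NULL) {
  V <- if (!is.null(robust_cluster)) robust_variance(fit, robust_cluster)
  out <- rate_ratios(fit, vcov = V)
  if (!is.null(keep)) out <- out[grepl(keep, out$term), , drop = FALSE]
  if (nrow(out)) out$flavour <- flavour
  out
}

#' Run the full overdose-risk analysis pipeline
#'
#' Executes, in order: analgesia-formulation cleaning, modality-switch
#' censoring, cohort eligibility and follow-up definition, treatment
#' episode construction, censor-variant application, risk-window
#' person-time splitting (with time-varying age bands), outcome
#' ascertainment and event attribution, propensity/IPW weighting with
#' balance diagnostics, unadjusted / adjusted / weighted rate-ratio
#' models (Poisson or negative binomial by overdispersion test;
#' cluster-robust variance for weighted fits), first-event Cox hazard
#' ratios, and E-values for the weighted modality contrasts.
#'
#' @param cohort an `oat_cohort` from [generate_cohort()], a list with
#'   elements patients, prescriptions, admissions, deaths, or a
#'   directory path readable by [read_cohort()].
#' @param code_lists a [code_list()]; default
#'   [oat_default_code_lists()].
#' @param supply_days,max_gap_days,overlap_mode episode-construction
#'   settings, see [build_episodes()].
#' @param window_days elevated-risk window length, default 28.
#' @param censor_variant,censor_years see [apply_censor_variants()].
#' @param covariates propensity/adjustment covariate names; `NULL`
#'   (default) uses age band, gender, IMD quintile, region plus any
#'   extra baseline flag columns found on the patients table.
#' @param model_family `"auto"` (overdispersion-tested, default),
#'   `"poisson"` or `"negbin"`.
#' @param matching diagnosis-code matching dialect, `"prefix"` or
#'   `"exact"`.
#' @param study_start,study_end global study window.
#' @param weight_truncate optional IPW truncation quantiles.
#' @param history_lookback_years lookback for the derived
#'   overdose-history flag when the patients table does not already
#'   carry one, default `Inf`.
#' @param output_dir if given, report tables are written there as
#'   tab-delimited text plus a JSON summary.
#' @param light fit only the treatment-status and risk-window rate
#'   models, skipping the modality-stratified, hazard-ratio and E-value
#'   steps; used by [run_sensitivity()] where only the window contrasts
#'   are compared (default FALSE).
#' @return list of class `oat_report`; see the package vignette for the
#'   components.
#' @export
run_pipeline <- function(cohort,
                         code_lists = oat_default_code_lists(),
                         supply_days = 14, max_gap_days = 14,
                         overlap_mode = "extend",
                         window_days = 28,
                         censor_variant = "none", censor_years = 10,
                         covariates = NULL,
                         model_family = c("auto", "poisson", "negbin"),
                         matching = "prefix",
                         study_start = "1998-01-01",
                         study_end = "2017-12-31",
                         weight_truncate = NULL,
                         history_lookback_years = Inf,
                         output_dir = NULL,
                         light = FALSE) {
  model_family <- match.arg(model_family)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  pat <- cohort$patients
  schema_cols <- c("patient_id", "birth_year", "gender", "region",
                   "imd_quintile", "reg_start", "reg_end")
  assert_columns(pat, schema_cols, "patients")

  ## exposure stream ------------------------------------------------------
  rx <- clean_prescriptions(cohort$prescriptions, code_lists)
  sw <- censor_at_switch(rx)
  fu0 <- make_follow_up(pat, sw$prescriptions, study_start, study_end,
                        deaths = cohort$deaths, switches = sw$switches)
  audit <- fu0$audit
  tie <- audit$patient_id %in% sw$excluded$patient_id & !audit$included
  audit$reason[tie] <- "modality_tie"
  fu <- fu0$follow_up
  eps <- suppressWarnings(
    build_episodes(sw$prescriptions, supply_days, max_gap_days,
                   overlap_mode, follow_up = fu))
  fu <- apply_censor_variants(fu, eps, censor_variant, censor_years)
  iv <- split_follow_up(eps, fu, window_days, patients = pat)
  iv$status <- factor(ifelse(iv$window %in% c("in_1_4", "in_gt4"),
                             "in", "out"), levels = c("in", "out"))

  ## ascertainment --------------------------------------------------------
  nonfatal <- classify_admissions(cohort$admissions, code_lists,
                                  matching = matching)
  fatal <- classify_deaths(cohort$deaths, code_lists, matching = matching)
  idx <- fu$index_date[match(nonfatal$patient_id, fu$patient_id)]
  oend <- fu$observation_end[match(nonfatal$patient_id, fu$patient_id)]
  in_fu <- !is.na(idx) & nonfatal$event_date >= idx &
    nonfatal$event_date < oend
  outcome_events <- nonfatal[in_fu, , drop = FALSE]
  pre_index <- nonfatal[!is.na(idx) & nonfatal$event_date < idx, ,
                        drop = FALSE]

  iv_multi <- suppressWarnings(attribute_events(iv, outcome_events))
  iv_first <- suppressWarnings(
    attribute_events(iv, outcome_events, first_event_only = TRUE))

  ## aggregates -----------------------------------------------------------
  rates <- list(
    status = aggregate_person_time(iv_multi, "status"),
    window = aggregate_person_time(iv_multi, "window"),
    window_by_drug = aggregate_person_time(iv_multi, c("window", "drug")),
    status_by_drug = aggregate_person_time(iv_multi, c("status", "drug")),
    incidence_status = aggregate_person_time(iv_first, "status"),
    incidence_window = aggregate_person_time(iv_first, "window"))

  ## baseline covariates and weights --------------------------------------
  drug0 <- tapply(sw$prescriptions$drug, sw$prescriptions$patient_id,
                  `[`, 1L)
  cov_df <- pat[match(fu$patient_id, pat$patient_id), , drop = FALSE]
  cov_df$drug <- factor(as.character(drug0[fu$patient_id]),
                        levels = DRUG_LEVELS)
  cov_df$age_band <- age_band(age_at(fu$index_date, cov_df$birth_year))
  cov_df$imd_quintile <- factor(cov_df$imd_quintile)
  if (is.null(covariates)) {
    extra <- setdiff(names(pat), schema_cols)
    covariates <- c("age_band", "gender", "imd_quintile", "region", extra)
  }
  if ("overdose_history" %in% covariates &&
      !"overdose_history" %in% names(cov_df)) {
    hist <- flag_history(pre_index,
                         fu[c("patient_id", "index_date")],
                         history_lookback_years)
    cov_df$overdose_history <- as.integer(hist$flag)
  }
  ps <- fit_propensity(cov_df, covariates)
  wts <- stabilised_ipw(ps, cov_df$drug, weight_truncate)
  balance <- merge(
    standardised_differences(cov_df, covariates),
    standardised_differences(cov_df, covariates, weights = wts),
    by = c("covariate", "level"), suffixes = c("_unweighted", "_weighted"),
    sort = FALSE)

  ## model records --------------------------------------------------------
  recordize <- function(ivx) {
    rec <- ivx
    rec$py <- rec$days / DAYS_PER_YEAR
    rec$window <- stats::relevel(rec$window, ref = "in_gt4")
    rec$drug <- factor(rec$drug, levels = DRUG_LEVELS)
    m <- match(rec$patient_id, fu$patient_id)
    rec$weight <- wts[m]
    for (v in setdiff(covariates, "age_band")) rec[[v]] <- cov_df[[v]][m]
    rec
  }
  rec <- recordize(iv_multi)
  adj_terms <- covariates

  fam <- resolve_family(rec, c("window", "drug"), model_family)
  cl <- rec$patient_id

  rr_tab <- function(terms, keep) {
    u <- fit_rate(rec, terms, fam)
    a <- fit_rate(rec, c(terms, adj_terms), fam)
    w <- fit_rate(rec, terms, fam, weights = rec$weight)
    rbind(flavoured_rrs(u, "uRR", keep = keep),
          flavoured_rrs(a, "aRR", keep = keep),
          flavoured_rrs(w, "wRR", robust_cluster = cl, keep = keep))
  }
  rr_status <- rr_tab("status", keep = "^status")
  rr_window <- rr_tab("window", keep = "^window")

  if (light) {
    return(structure(list(
      settings = list(supply_days = supply_days,
                      max_gap_days = max_gap_days,
                      overlap_mode = overlap_mode,
                      window_days = window_days,
                      censor_variant = censor_variant,
                      censor_years = censor_years,
                      covariates = covariates, model_family = fam,
                      matching = matching, light = TRUE),
      audit = audit, follow_up = fu, episodes = eps,
      intervals = iv_multi, rates = rates,
      weights = wts, balance = balance,
      rr_status = rr_status, rr_window = rr_window,
      rr_modality = NULL, hr_modality = NULL, evalues = NULL,
      n_events_attributed = sum(iv_multi$events),
      n_events_dropped = attr(iv_multi, "n_dropped")),
      class = "oat_report"))
  }

  rr_mod <- function(subset_status = NULL) {
    r <- if (is.null(subset_status)) rec else
      rec[rec$status == subset_status, , drop = FALSE]
    u <- fit_rate(r, "drug", fam)
    a <- fit_rate(r, c("drug", adj_terms), fam)
    w <- fit_rate(r, "drug", fam, weights = r$weight)
    out <- rbind(flavoured_rrs(u, "uRR", keep = "^drug"),
                 flavoured_rrs(a, "aRR", keep = "^drug"),
                 flavoured_rrs(w, "wRR", robust_cluster = r$patient_id,
                               keep = "^drug"))
    out$stratum <- subset_status %||% "all"
    out
  }
  rr_modality <- rbind(rr_mod(), rr_mod("in"), rr_mod("out"))

  ## first-event hazard ratios --------------------------------------------
  cox_rec <- recordize(iv_first)
  m <- match(cox_rec$patient_id, fu$patient_id)
  idx0 <- as.integer(fu$index_date)[m]
  cox_rec$tstart <- as.integer(cox_rec$start) - idx0
  cox_rec$tstop <- as.integer(cox_rec$end) - idx0
  cox_rec$event <- cox_rec$events
  hr_modality <- tryCatch({
    u <- fit_cox_first_event(cox_rec, "drug")
    a <- fit_cox_first_event(cox_rec, c("drug", adj_terms))
    w <- fit_cox_first_event(cox_rec, "drug", weights = cox_rec$weight)
    rbind(flavoured_rrs(u, "uHR", keep = "^drug"),
          flavoured_rrs(a, "aHR", keep = "^drug"),
          flavoured_rrs(w, "wHR", keep = "^drug"))
  }, error = function(e) {
    warning("hazard-ratio models skipped: ", conditionMessage(e))
    NULL
  })

  ## E-values --------------------------------------------------------------
  wrr <- rr_modality[rr_modality$flavour == "wRR", , drop = FALSE]
  evalues <- do.call(rbind, lapply(seq_len(nrow(wrr)), function(i) {
    e <- e_value(wrr$estimate[i], wrr$conf_low[i], wrr$conf_high[i])
    data.frame(contrast = paste0("buprenorphine_vs_methadone_",
                                 wrr$stratum[i]),
               rr = e$rr, conf_low = e$ci_low, conf_high = e$ci_high,
               e_point = e$e_point, e_ci = e$e_ci,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    settings = list(supply_days = supply_days,
                    max_gap_days = max_gap_days,
                    overlap_mode = overlap_mode,
                    window_days = window_days,
                    censor_variant = censor_variant,
                    censor_years = censor_years,
                    covariates = covariates, model_family = fam,
                    matching = matching,
                    study_start = study_start, study_end = study_end),
    audit = audit,
    follow_up = fu, episodes = eps,
    episode_summary = episode_summaries(eps, fu),
    intervals = iv_multi, first_event_intervals = iv_first,
    rates = rates,
    propensity = ps, weights = wts, balance = balance,
    rr_status = rr_status, rr_window = rr_window,
    rr_modality = rr_modality, hr_modality = hr_modality,
    evalues = evalues,
    n_events_attributed = sum(iv_multi$events),
    n_events_dropped = attr(iv_multi, "n_dropped")),
    class = "oat_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.oat_report <- function(x, ...) {
  cat("Opioid agonist treatment overdose-risk analysis\n")
  cat(sprintf("  patients included: %d of %d\n",
              sum(x$audit$included), nrow(x$audit)))
  cat(sprintf("  events attributed: %d (%d dropped)\n",
              x$n_events_attributed, x$n_events_dropped))
  cat(sprintf("  model family: %s\n", x$settings$model_family))
  w <- x$rr_window[x$rr_window$flavour == "wRR", ]
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  wRR %-18s %5.2f (%.2f-%.2f)\n",
                sub("^window", "", w$term[i]), w$estimate[i],
                w$conf_low[i], w$conf_high[i]))
  }
  m <- if (is.null(x$rr_modality)) data.frame() else
    x$rr_modality[x$rr_modality$flavour == "wRR" &
                    x$rr_modality$stratum == "all", ]
  if (nrow(m)) {
    cat(sprintf("  wRR buprenorphine vs methadone: %.2f (%.2f-%.2f)\n",
                m$estimate, m$conf_low, m$conf_high))
  }
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm) {
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$balance, "baseline_balance")
  wt(report$rates$window, "event_rates_window")
  wt(report$rates$window_by_drug, "event_rates_window_by_drug")
  wt(report$rates$incidence_window, "incidence_rates_window")
  wt(report$rr_status, "rate_ratios_status")
  wt(report$rr_window, "rate_ratios_window")
  wt(report$rr_modality, "rate_ratios_modality")
  if (!is.null(report$hr_modality)) wt(report$hr_modality,
                                       "hazard_ratios_modality")
  wt(report$evalues, "evalues")
  wt(report$audit, "audit")
  jsonlite::write_json(report$settings, file.path(dir, "settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sensitivity analyses over exposure-definition variants
#'
#' Re-runs the pipeline under a 7-day assumed supply, a 7-day maximum
#' gap, and one-year-post-treatment outcome censoring, and tabulates
#' whether each risk-window rate ratio keeps its direction (above or
#' below 1) relative to the base analysis.
#'
#' @param cohort as in [run_pipeline()].
#' @param light pass `light = TRUE` to every run (default), fitting
#'   only the window and status models that the direction comparison
#'   needs.
#' @param ... further arguments passed to every [run_pipeline()] call.
#' @return list with `reports` (named list of `oat_report`) and
#'   `directions` (data frame of sign agreement per window contrast and
#'   variant).
#' @export
run_sensitivity <- function(cohort, light = TRUE, ...) {
  variants <- list(
    base = list(),
    supply_7d = list(supply_days = 7),
    gap_7d = list(max_gap_days = 7),
    censor_1y = list(censor_variant = "one_year_post_treatment"))
  reports <- lapply(variants, function(v) {
    do.call(run_pipeline, c(list(cohort = cohort, light = light), v,
                            list(...)))
  })
  base_w <- reports$base$rr_window
  base_w <- base_w[base_w$flavour == "wRR", ]
  dirs <- do.call(rbind, lapply(names(reports), function(nm) {
    w <- reports[[nm]]$rr_window
    w <- w[w$flavour == "wRR", ]
    data.frame(variant = nm, term = w$term, estimate = w$estimate,
               direction = ifelse(w$estimate >= 1, "above_1", "below_1"),
               agrees_with_base = ifelse(
                 (w$estimate >= 1) ==
                   (base_w$estimate[match(w$term, base_w$term)] >= 1),
                 TRUE, FALSE),
               stringsAsFactors = FALSE)
  }))
  list(reports = reports, directions = dirs)
}
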