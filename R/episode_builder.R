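# Treatment-episode construction from prescription issue dates.
#
# OAT scripts in England are issued for at most 14 days of supply, so each
# prescription is assumed to cover [issue, issue + supply_days). Episodes
# are maximal runs of prescriptions whose inter-prescription gaps (issue of
# the next minus expiry of the current) stay below a maximum gap;
# overlapping or duplicated prescriptions extend the running expiry.
# All intervals are half-open [start, end).

#' Remove analgesia-formulation prescriptions
#'
#' Drops prescription records whose product code belongs to the
#' `analgesia_exclusion` category of the supplied code list (e.g.
#' transdermal buprenorphine patches, methadone linctus), which indicate
#' prescribing for pain relief rather than opioid agonist treatment.
#'
#' @param prescriptions data frame with columns patient_id, issue_date,
#'   drug, product_code.
#' @param exclusion_list a [code_list()] whose `PRODUCT` entries in
#'   category `analgesia_exclusion` define the exclusions; `NULL` for no
#'   exclusions.
#' @param matching `"exact"` (default for product codes) or `"prefix"`.
#' @return the filtered prescriptions; attribute `n_removed` records the
#'   number of dropped rows. Warns if nothing remains.
#' @export
clean_prescriptions <- function(prescriptions, exclusion_list = NULL,
                                matching = c("exact", "prefix")) {
  matching <- match.arg(matching)
  assert_columns(prescriptions,
                 c("patient_id", "issue_date", "drug", "product_code"),
                 "prescriptions")
  removed <- 0L
  out <- prescriptions
  if (!is.null(exclusion_list)) {
    if (!inherits(exclusion_list, "code_list")) {
      exclusion_list <- code_list(exclusion_list)
    }
    excl <- codes_for(exclusion_list, "analgesia_exclusion", "PRODUCT")
    hit <- match_codes(out$product_code, excl, matching)
    removed <- sum(hit)
    out <- out[!hit, , drop = FALSE]
  }
  if (!nrow(out)) warning("no prescriptions remain after exclusions")
  attr(out, "n_removed") <- removed
  out
}

#' Censor prescription streams at modality switch
#'
#' Patients contribute follow-up under one treatment modality only. For a
#' patient whose records contain both methadone and buprenorphine, the
#' modality is the drug of the earliest prescription, all prescriptions of
#' that drug strictly before the first issue of the other drug are kept,
#' and the first issue date of the other drug is recorded as the switch
#' date at which observation is later censored. Patients whose very first
#' methadone and buprenorphine prescriptions share a date cannot be
#' assigned a modality and are excluded with reason `modality_tie`.
#'
#' @param prescriptions data frame with columns patient_id, issue_date,
#'   drug (plus any others, carried through).
#' @return list with elements `prescriptions` (single-drug streams),
#'   `switches` (patient_id, switch_date) and `excluded` (patient_id,
#'   reason).
#' @export
censor_at_switch <- function(prescriptions) {
  assert_columns(prescriptions, c("patient_id", "issue_date", "drug"),
                 "prescriptions")
  rx <- prescriptions
  rx$issue_date <- as_date(rx$issue_date)
  rx <- rx[order(rx$patient_id, rx$issue_date), , drop = FALSE]

  keep <- rep(TRUE, nrow(rx))
  sw_id <- character(0); sw_date <- as.Date(character(0))
  ex_id <- character(0)
  nd <- tapply(rx$drug, rx$patient_id, function(d) length(unique(d)))
  for (pid in names(nd)[nd > 1L]) {
    i <- which(rx$patient_id == pid)
    d0 <- rx$issue_date[i[1]]
    first_drug <- rx$drug[i[1]]
    if (any(rx$issue_date[i] == d0 & rx$drug[i] != first_drug)) {
      keep[i] <- FALSE
      ex_id <- c(ex_id, pid)
      next
    }
    switch_date <- min(rx$issue_date[i][rx$drug[i] != first_drug])
    keep[i] <- keep[i] & rx$drug[i] == first_drug &
      rx$issue_date[i] < switch_date
    sw_id <- c(sw_id, pid)
    sw_date <- c(sw_date, switch_date)
  }
  list(prescriptions = rx[keep, , drop = FALSE],
       switches = data.frame(patient_id = sw_id, switch_date = sw_date,
                             stringsAsFactors = FALSE),
       excluded = data.frame(patient_id = ex_id,
                             reason = rep("modality_tie", length(ex_id)),
                             stringsAsFactors = FALSE))
}

#' Define cohort entry and follow-up per patient
#'
#' The index date is the first eligible prescription's issue date.
#' Eligibility requires age within `age_range` at index and at least
#' `min_registration_days` of registration before index. Observation ends
#' at the earliest of registration end, death, the global study end and
#' (if present) the modality switch date.
#'
#' @param patients data frame with columns patient_id, birth_year,
#'   reg_start, reg_end.
#' @param prescriptions cleaned, switch-censored prescription stream.
#' @param study_start,study_end global observation window (ISO dates).
#'   Deaths registered after `study_end` never shorten follow-up
#'   (mortality-registration censor).
#' @param deaths optional data frame with patient_id, death_date.
#' @param switches optional data frame from [censor_at_switch()].
#' @param min_registration_days minimum prior registration, default 30.
#' @param age_range inclusive age bounds at index, default `c(18, 64)`.
#' @return list with `follow_up` (patient_id, index_date,
#'   observation_end) for included patients, and `audit` (patient_id,
#'   included, reason) covering every patient in `patients`.
#' @export
make_follow_up <- function(patients, prescriptions,
                           study_start = "1998-01-01",
                           study_end = "2017-12-31",
                           deaths = NULL, switches = NULL,
                           min_registration_days = 30,
                           age_range = c(18, 64)) {
  assert_columns(patients, c("patient_id", "birth_year", "reg_start",
                             "reg_end"), "patients")
  study_start <- as_date(study_start)
  study_end <- as_date(study_end)
  rx <- prescriptions
  rx$issue_date <- as_date(rx$issue_date)
  idx <- tapply(as.integer(rx$issue_date), rx$patient_id, min)
  index_date <- as.Date(as.integer(idx[match(patients$patient_id,
                                             names(idx))]),
                        origin = "1970-01-01")

  age <- age_at(index_date, patients$birth_year)
  reg_start <- as_date(patients$reg_start)
  reg_end <- as_date(patients$reg_end)

  end <- pmin(reg_end, study_end)
  if (!is.null(deaths) && nrow(deaths)) {
    dd <- as_date(deaths$death_date)[match(patients$patient_id,
                                           deaths$patient_id)]
    dd[!is.na(dd) & dd > study_end] <- NA  # registration-delay censor
    end <- pmin(end, dd, na.rm = TRUE)
  }
  if (!is.null(switches) && nrow(switches)) {
    sw <- as_date(switches$switch_date)[match(patients$patient_id,
                                              switches$patient_id)]
    end <- pmin(end, sw, na.rm = TRUE)
  }
  # half-open follow-up [index, end); death/switch on day d retains day d
  end <- pmax(end, index_date, na.rm = FALSE)

  reason <- rep(NA_character_, nrow(patients))
  reason[is.na(index_date)] <- "no_eligible_prescription"
  sel <- is.na(reason) & (age < age_range[1] | age > age_range[2])
  reason[sel] <- "age_out_of_range"
  sel <- is.na(reason) &
    as.numeric(index_date - reg_start) < min_registration_days
  reason[sel] <- "insufficient_registration"
  sel <- is.na(reason) & (index_date < study_start | index_date > study_end)
  reason[sel] <- "index_outside_study_period"
  sel <- is.na(reason) & end <= index_date
  reason[sel] <- "no_follow_up"

  included <- is.na(reason)
  list(follow_up = data.frame(patient_id = patients$patient_id[included],
                              index_date = index_date[included],
                              observation_end = end[included],
                              stringsAsFactors = FALSE),
       audit = data.frame(patient_id = patients$patient_id,
                          included = included,
                          reason = ifelse(included, "included", reason),
                          stringsAsFactors = FALSE))
}

episodes_one_patient <- function(days, supply_days, max_gap_days,
                                 overlap_mode) {
  start <- days[1]; expiry <- days[1] + supply_days; n <- 1L
  starts <- integer(0); ends <- integer(0); ns <- integer(0)
  for (d in days[-1]) {
    if (d < expiry) {
      # overlapping or duplicated prescription: extend the running expiry.
      # "extend" never shortens exposure; "stack" adds a full supply.
      expiry <- if (overlap_mode == "extend") max(expiry, d + supply_days)
                else expiry + supply_days
      n <- n + 1L
    } else if (d - expiry < max_gap_days) {
      expiry <- d + supply_days
      n <- n + 1L
    } else {
      starts <- c(starts, start); ends <- c(ends, expiry); ns <- c(ns, n)
      start <- d; expiry <- d + supply_days; n <- 1L
    }
  }
  cbind(start = c(starts, start), end = c(ends, expiry), n_rx = c(ns, n))
}

#' Build treatment episodes from a prescription stream
#'
#' Each prescription covers `[issue, issue + supply_days)`. A subsequent
#' prescription continues the current episode when the gap between the
#' running expiry and its issue date is strictly less than
#' `max_gap_days`; a gap of `max_gap_days` or more closes the episode at
#' the running expiry and opens an out-of-treatment period. A
#' prescription issued before the running expiry ("overlapping or
#' duplicated") extends the expiry: in `overlap_mode = "extend"` the new
#' expiry is the later of the current expiry and issue + `supply_days`
#' (instalment dispensing); in `"stack"` a full `supply_days` is added to
#' the current expiry.
#'
#' @param prescriptions single-drug-per-patient stream with columns
#'   patient_id, issue_date, drug. Exact duplicate (patient, date) rows
#'   are collapsed; unsorted input is sorted with a warning.
#' @param supply_days assumed supply per prescription, default 14.
#' @param max_gap_days maximum permissible gap, default 14.
#' @param overlap_mode `"extend"` (default) or `"stack"`.
#' @param follow_up optional [make_follow_up()] spec; prescriptions issued
#'   outside `[index, observation_end)` are dropped with a warning.
#' @return data frame of episodes: patient_id, drug, start, end
#'   (half-open Dates), n_rx; per patient episodes are disjoint and
#'   sorted.
#' @export
build_episodes <- function(prescriptions, supply_days = 14,
                           max_gap_days = 14,
                           overlap_mode = c("extend", "stack"),
                           follow_up = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  assert_columns(prescriptions, c("patient_id", "issue_date", "drug"),
                 "prescriptions")
  if (supply_days < 1 || max_gap_days < 1) {
    stop("supply_days and max_gap_days must be positive", call. = FALSE)
  }
  rx <- prescriptions
  rx$issue_date <- as_date(rx$issue_date)
  ndrug <- tapply(rx$drug, rx$patient_id, function(d) length(unique(d)))
  if (any(ndrug > 1L)) {
    stop("patients with more than one drug in the stream; ",
         "run censor_at_switch() first", call. = FALSE)
  }
  if (!is.null(follow_up)) {
    fu_idx <- as_date(follow_up$index_date)[
      match(rx$patient_id, follow_up$patient_id)]
    fu_end <- as_date(follow_up$observation_end)[
      match(rx$patient_id, follow_up$patient_id)]
    out <- is.na(fu_idx) | rx$issue_date < fu_idx | rx$issue_date >= fu_end
    if (any(out)) {
      warning(sprintf("%d prescription(s) outside follow-up dropped",
                      sum(out)))
      rx <- rx[!out, , drop = FALSE]
    }
  }
  rx <- rx[!duplicated(rx[c("patient_id", "issue_date")]), , drop = FALSE]
  ord <- order(rx$patient_id, rx$issue_date)
  if (is.unsorted(ord)) {
    warning("prescriptions not sorted by patient and issue date; sorting")
    rx <- rx[ord, , drop = FALSE]
  }
  if (!nrow(rx)) {
    return(data.frame(patient_id = character(), drug = character(),
                      start = as.Date(character()),
                      end = as.Date(character()), n_rx = integer(),
                      stringsAsFactors = FALSE))
  }
  days_by_pat <- split(as.integer(rx$issue_date), rx$patient_id)
  drug_by_pat <- vapply(split(rx$drug, rx$patient_id), `[`, "", 1L)
  eps <- lapply(days_by_pat, episodes_one_patient,
                supply_days = supply_days, max_gap_days = max_gap_days,
                overlap_mode = overlap_mode)
  nep <- vapply(eps, nrow, 0L)
  m <- do.call(rbind, eps)
  data.frame(patient_id = rep(names(eps), nep),
             drug = rep(unname(drug_by_pat), nep),
             start = as.Date(m[, "start"], origin = "1970-01-01"),
             end = as.Date(m[, "end"], origin = "1970-01-01"),
             n_rx = as.integer(m[, "n_rx"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise treatment episodes per modality
#'
#' Reports, per drug: number of patients and episodes, median (IQR) days
#' in and out of treatment per patient and per episode, and the
#' distribution of episode durations over the bands up to 1 month, 1-3,
#' 3-6, 6-12 and more than 12 months (1 month = 30.44 days).
#'
#' @param episodes data frame from [build_episodes()].
#' @param follow_up follow-up spec from [make_follow_up()].
#' @return list with `by_modality` (summary statistics) and `bands`
#'   (episode counts and percentages per duration band and drug).
#' @export
episode_summaries <- function(episodes, follow_up) {
  if (!nrow(episodes)) {
    return(list(by_modality = data.frame(), bands = data.frame()))
  }
  ep <- episodes
  ep$days <- as.numeric(as_date(ep$end) - as_date(ep$start))
  fu <- follow_up
  fu$fu_days <- as.numeric(as_date(fu$observation_end) -
                             as_date(fu$index_date))
  # observed days in treatment clip episodes to follow-up
  idx <- as_date(fu$index_date)[match(ep$patient_id, fu$patient_id)]
  oe <- as_date(fu$observation_end)[match(ep$patient_id, fu$patient_id)]
  ep$obs_days <- pmax(0, as.numeric(pmin(as_date(ep$end), oe) -
                                      pmax(as_date(ep$start), idx)))

  per_pat <- stats::aggregate(obs_days ~ patient_id + drug, data = ep, sum)
  per_pat$fu_days <- fu$fu_days[match(per_pat$patient_id, fu$patient_id)]
  per_pat$out_days <- per_pat$fu_days - per_pat$obs_days

  q3 <- function(x) stats::quantile(x, c(.25, .5, .75), names = FALSE)
  by_mod <- do.call(rbind, lapply(split(seq_len(nrow(per_pat)),
                                        per_pat$drug), function(i) {
    pid <- per_pat$patient_id[i]
    e <- ep[ep$patient_id %in% pid, ]
    qin <- q3(per_pat$obs_days[i]); qout <- q3(per_pat$out_days[i])
    qep <- q3(e$days)
    data.frame(drug = per_pat$drug[i][1], n_patients = length(i),
               n_episodes = nrow(e),
               episodes_median = stats::median(
                 as.numeric(table(e$patient_id))),
               days_in_median = qin[2], days_in_q1 = qin[1],
               days_in_q3 = qin[3],
               days_out_median = qout[2], days_out_q1 = qout[1],
               days_out_q3 = qout[3],
               episode_days_median = qep[2], episode_days_q1 = qep[1],
               episode_days_q3 = qep[3],
               stringsAsFactors = FALSE)
  }))
  row.names(by_mod) <- NULL

  band <- cut(ep$days / DAYS_PER_MONTH,
              breaks = c(0, 1, 3, 6, 12, Inf),
              labels = c("up to 1 month", "1-3 months", "3-6 months",
                         "6-12 months", "> 12 months"))
  tab <- as.data.frame(table(drug = ep$drug, band = band),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$drug, sum)
  tab$pct <- 100 * tab$n / as.numeric(tot[tab$drug])
  list(by_modality = by_mod, bands = tab)
}
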