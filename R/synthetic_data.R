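# Synthetic-cohort generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: prescription
# cascades with gaps, overlaps and modality switches; confounding by
# indication through baseline covariates that raise both the odds of
# methadone (vs buprenorphine) receipt and the overdose hazard; and a
# piecewise-constant overdose hazard that is elevated in the first four
# weeks in and out of treatment. Every draw descends from one root seed,
# and a per-patient latent exposure ledger is kept so expected event
# counts per stratum can be computed analytically.

#' Simulation configuration
#'
#' @param n_patients number of patients (>= 1).
#' @param seed root random seed; identical configuration and seed give
#'   byte-identical cohorts.
#' @param baseline_hazard overdose events per person-year in the
#'   reference stratum (methadone, more than four weeks into a
#'   treatment episode). Default 0.10.
#' @param window_rr named true rate ratios for exactly the four risk
#'   windows `in_1_4`, `in_gt4`, `out_1_4`, `out_gt4`, with
#'   `in_gt4 = 1` as reference. Defaults 5.5 / 1 / 13 / 1.4, the
#'   elevated initiation and cessation risks the analysis targets.
#' @param modality_rr true buprenorphine-vs-methadone rate ratio,
#'   default 0.4 (buprenorphine protective).
#' @param confounders data frame with columns name, prevalence,
#'   assign_log_odds (effect on the log-odds of buprenorphine
#'   assignment), rate_log_rr (effect on the log overdose rate).
#'   Negative assignment effects with positive rate effects encode
#'   confounding by indication: sicker patients get methadone and
#'   overdose more.
#' @param assignment_intercept intercept of the buprenorphine assignment
#'   logit; the default (-0.67) yields roughly 27% buprenorphine under
#'   the default confounders.
#' @param episode_spec list controlling the prescription process:
#'   `mean_rx_per_episode` (geometric, default 3.5),
#'   `issue_interval_days` (uniform inclusive range between successive
#'   issues within an episode, default c(7, 27) so gaps stay below 14
#'   days and some prescriptions overlap), `out_gap_mean_days`
#'   (exponential mean of the out-of-treatment gap beyond the minimum,
#'   default 76), `min_out_gap_days` (default 14), `switch_prob`
#'   (probability a patient eventually switches modality, default 0.15),
#'   `analgesia_rx_prob` (probability of carrying analgesia-formulation
#'   noise prescriptions, default 0.05).
#' @param supply_days assumed supply per prescription (default 14); the
#'   latent episodes end `supply_days` after their last issue.
#' @param follow_up_years maximum follow-up per patient (default 10).
#' @param follow_up_mean_years mean of the exponential registration
#'   length (default 3; median about 2 years).
#' @param noise_admission_rate rate (per person-year) of non-overdose
#'   hospital admissions, default 0.3.
#' @param fatal_od_rate fatal-overdose death rate per person-year,
#'   default 0.004.
#' @param other_death_rate other-cause death rate per person-year,
#'   default 0.008.
#' @param study_start,study_end global study window (ISO dates).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1,
                       baseline_hazard = 0.10,
                       window_rr = c(in_1_4 = 5.5, in_gt4 = 1,
                                     out_1_4 = 13, out_gt4 = 1.4),
                       modality_rr = 0.4,
                       confounders = default_confounders(),
                       assignment_intercept = -0.67,
                       episode_spec = list(),
                       supply_days = 14,
                       follow_up_years = 10,
                       follow_up_mean_years = 3,
                       noise_admission_rate = 0.3,
                       fatal_od_rate = 0.004,
                       other_death_rate = 0.008,
                       study_start = "1998-01-01",
                       study_end = "2017-12-31") {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop_config("n_patients", "must be >= 1")
  }
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    stop_config("baseline_hazard", "must be > 0")
  }
  if (!setequal(names(window_rr), WINDOW_LEVELS) ||
      length(window_rr) != 4L) {
    stop_config("window_rr", paste("must carry exactly the labels",
                                   paste(WINDOW_LEVELS, collapse = ", ")))
  }
  window_rr <- window_rr[WINDOW_LEVELS]
  if (any(!is.finite(window_rr)) || any(window_rr <= 0)) {
    stop_config("window_rr", "all rate ratios must be strictly positive")
  }
  if (abs(window_rr[["in_gt4"]] - 1) > 1e-12) {
    stop_config("window_rr", "in_gt4 is the reference and must equal 1")
  }
  if (!is.numeric(modality_rr) || modality_rr <= 0) {
    stop_config("modality_rr", "must be > 0")
  }
  if (!is.data.frame(confounders) ||
      !all(c("name", "prevalence", "assign_log_odds", "rate_log_rr") %in%
             names(confounders))) {
    stop_config("confounders",
                "needs columns name, prevalence, assign_log_odds, rate_log_rr")
  }
  if (nrow(confounders) &&
      (any(confounders$prevalence < 0) || any(confounders$prevalence > 1))) {
    stop_config("confounders", "prevalences must lie in [0, 1]")
  }
  es <- utils::modifyList(list(mean_rx_per_episode = 3.5,
                               issue_interval_days = c(7, 27),
                               out_gap_mean_days = 76,
                               min_out_gap_days = 14,
                               switch_prob = 0.15,
                               analgesia_rx_prob = 0.05), episode_spec)
  if (es$mean_rx_per_episode < 1) {
    stop_config("episode_spec$mean_rx_per_episode", "must be >= 1")
  }
  if (es$switch_prob < 0 || es$switch_prob > 1) {
    stop_config("episode_spec$switch_prob", "must lie in [0, 1]")
  }
  if (follow_up_years <= 0) stop_config("follow_up_years", "must be > 0")
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              baseline_hazard = baseline_hazard, window_rr = window_rr,
              modality_rr = modality_rr, confounders = confounders,
              assignment_intercept = assignment_intercept,
              episode_spec = es, supply_days = supply_days,
              follow_up_years = follow_up_years,
              follow_up_mean_years = follow_up_mean_years,
              noise_admission_rate = noise_admission_rate,
              fatal_od_rate = fatal_od_rate,
              other_death_rate = other_death_rate,
              study_start = as_date(study_start),
              study_end = as_date(study_end))
  class(cfg) <- "sim_config"
  cfg
}

#' Default confounders-by-indication specification
#'
#' Two baseline flags that lower the odds of buprenorphine assignment
#' and raise the overdose rate, so the crude modality contrast is biased
#' away from the truth while weighting can recover it.
#'
#' @return data frame with columns name, prevalence, assign_log_odds,
#'   rate_log_rr.
#' @export
default_confounders <- function() {
  data.frame(name = c("overdose_history", "benzodiazepine_use"),
             prevalence = c(0.20, 0.25),
             assign_log_odds = c(-1.0, -0.5),
             rate_log_rr = c(1.0, 0.5),
             stringsAsFactors = FALSE)
}

NONFATAL_OD_CODES <- c("T40.0", "T40.1", "T40.2", "T40.3", "T40.6",
                       "T43.6")
NOISE_ADM_CODES <- c("J18.9", "S72.0", "K35.8", "L03.1", "A41.9")
FATAL_OD_CODE <- "X42"
OTHER_DEATH_CODE <- "I21.9"

# Latent risk-window ledger for one patient: episodes are (start, end)
# day offsets from index with a drug each; follow-up is [0, fu_days).
# Written directly from the latent episode structure (not via the
# episode-reconstruction code under test).
ledger_one_patient <- function(ep_start, ep_end, ep_drug, fu_days,
                               window_days = 28) {
  s <- numeric(0); e <- numeric(0); w <- character(0); d <- character(0)
  put <- function(a, b, anchor, side, drug) {
    b <- min(b, fu_days); a <- max(a, 0)
    if (b <= a) return()
    cut <- min(max(anchor + window_days, a), b)
    if (cut > a) {
      s <<- c(s, a); e <<- c(e, cut)
      w <<- c(w, paste0(side, "_1_4")); d <<- c(d, drug)
    }
    if (b > cut) {
      s <<- c(s, cut); e <<- c(e, b)
      w <<- c(w, paste0(side, "_gt4")); d <<- c(d, drug)
    }
  }
  cur <- 0
  for (j in seq_along(ep_start)) {
    if (ep_start[j] >= fu_days) break
    if (ep_start[j] > cur) {
      put(cur, ep_start[j], cur, "out", ep_drug[max(1L, j - 1L)])
    }
    put(ep_start[j], ep_end[j], ep_start[j], "in", ep_drug[j])
    cur <- ep_end[j]
    if (cur >= fu_days) break
  }
  if (cur < fu_days) put(cur, fu_days, cur, "out",
                         ep_drug[max(1L, sum(ep_start < fu_days))])
  list(s = s, e = e, w = w, d = d)
}

#' Generate a synthetic OAT cohort with known ground truth
#'
#' Draws baseline covariates, assigns modality by a logistic model on
#' those covariates, simulates prescription cascades (with instalment
#' overlaps, continuation gaps below 14 days, out-of-treatment gaps of
#' at least 14 days and occasional modality switches), and generates
#' non-fatal overdose admissions from a piecewise-constant-hazard
#' Poisson process whose rate in each latent person-time segment is
#' baseline_hazard x window_rr x modality_rr^(buprenorphine) x
#' exp(covariate effects). Non-overdose noise admissions, pre-index
#' overdose-history admissions, and fatal overdose / other-cause deaths
#' (which censor follow-up) are generated alongside.
#'
#' @param config a [sim_config()].
#' @return list of class `oat_cohort` with elements `patients`,
#'   `prescriptions`, `admissions`, `deaths` (data frames in the
#'   pipeline's input schema) and `ground_truth` (the realised
#'   parameters, per-patient follow-up, switch days and the latent
#'   person-time ledger).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_patients
  es <- cfg$episode_spec
  ids <- sprintf("P%06d", seq_len(n))

  ## --- baseline ---------------------------------------------------------
  study_span <- as.integer(cfg$study_end - cfg$study_start)
  index_date <- cfg$study_start +
    sample.int(max(study_span - 365L, 1L), n, replace = TRUE)
  age0 <- sample(18:64, n, replace = TRUE,
                 prob = stats::dnorm(18:64, mean = 35, sd = 10))
  birth_year <- as.integer(format(index_date, "%Y")) - age0
  gender <- sample(c("male", "female"), n, TRUE, prob = c(0.70, 0.30))
  region <- sample(c("north", "midlands", "london", "south"), n, TRUE,
                   prob = c(0.30, 0.20, 0.15, 0.35))
  imd <- sample(1:5, n, TRUE, prob = c(0.06, 0.09, 0.14, 0.25, 0.46))
  reg_start <- index_date - sample(400:3000, n, replace = TRUE)

  nconf <- nrow(cfg$confounders)
  X <- matrix(0L, n, nconf,
              dimnames = list(NULL, cfg$confounders$name))
  for (j in seq_len(nconf)) {
    X[, j] <- stats::rbinom(n, 1L, cfg$confounders$prevalence[j])
  }

  lin_assign <- cfg$assignment_intercept +
    as.numeric(X %*% cfg$confounders$assign_log_odds)
  is_bup <- stats::rbinom(n, 1L, stats::plogis(lin_assign)) == 1L
  drug0 <- ifelse(is_bup, "buprenorphine", "methadone")
  log_rate_x <- as.numeric(X %*% cfg$confounders$rate_log_rr)

  ## --- follow-up and deaths --------------------------------------------
  reg_days <- pmin(pmax(round(stats::rexp(
    n, 1 / (cfg$follow_up_mean_years * DAYS_PER_YEAR))), 180),
    round(cfg$follow_up_years * DAYS_PER_YEAR))
  cap_days <- as.integer(cfg$study_end - index_date)
  t_od_death <- floor(stats::rexp(n, cfg$fatal_od_rate / DAYS_PER_YEAR))
  t_other_death <- floor(stats::rexp(n,
                                     cfg$other_death_rate / DAYS_PER_YEAR))
  fu_days <- pmin(reg_days, cap_days, t_od_death, t_other_death)
  fu_days <- pmax(fu_days, 1L)
  died_od <- t_od_death <= pmin(reg_days, cap_days, t_other_death) &
    t_od_death == fu_days
  died_other <- !died_od & t_other_death == fu_days &
    t_other_death <= pmin(reg_days, cap_days)
  reg_end <- index_date + reg_days

  ## --- prescription cascades and latent episodes -----------------------
  p_geom <- 1 / es$mean_rx_per_episode
  iv_lo <- es$issue_interval_days[1]; iv_hi <- es$issue_interval_days[2]
  will_switch <- stats::runif(n) < es$switch_prob
  switch_at_ep <- ifelse(will_switch, sample(2:5, n, replace = TRUE), Inf)

  rx_pid <- vector("list", n); rx_day <- vector("list", n)
  rx_drug <- vector("list", n)
  led <- vector("list", n)
  switch_day <- rep(NA_integer_, n)

  other_drug <- function(d) if (d == "methadone") "buprenorphine" else
    "methadone"

  for (i in seq_len(n)) {
    t <- 0; k <- 0L; cur_drug <- drug0[i]
    eps_s <- numeric(0); eps_e <- numeric(0); eps_d <- character(0)
    days_i <- numeric(0); drugs_i <- character(0)
    while (t < fu_days[i]) {
      k <- k + 1L
      if (k == switch_at_ep[i]) {
        cur_drug <- other_drug(cur_drug)
        switch_day[i] <- as.integer(t)
      }
      n_rx <- 1L + stats::rgeom(1L, p_geom)
      gaps <- if (n_rx > 1L) sample(iv_lo:iv_hi, n_rx - 1L,
                                    replace = TRUE) else integer(0)
      issues <- t + cumsum(c(0, gaps))
      issues <- issues[issues < fu_days[i]]
      if (!length(issues)) break
      days_i <- c(days_i, issues)
      drugs_i <- c(drugs_i, rep(cur_drug, length(issues)))
      ep_end <- max(issues) + cfg$supply_days
      eps_s <- c(eps_s, t); eps_e <- c(eps_e, ep_end)
      eps_d <- c(eps_d, cur_drug)
      t <- ep_end + es$min_out_gap_days +
        round(stats::rexp(1L, 1 / es$out_gap_mean_days))
    }
    if (!length(eps_s)) { # degenerate: keep a single index prescription
      days_i <- 0; drugs_i <- cur_drug
      eps_s <- 0; eps_e <- cfg$supply_days; eps_d <- cur_drug
    }
    rx_pid[[i]] <- rep(ids[i], length(days_i))
    rx_day[[i]] <- days_i
    rx_drug[[i]] <- drugs_i
    led[[i]] <- ledger_one_patient(eps_s, eps_e, eps_d, fu_days[i])
  }

  led_n <- vapply(led, function(l) length(l$s), 0L)
  ledger <- data.frame(
    patient_id = rep(ids, led_n),
    start = unlist(lapply(led, `[[`, "s")),
    end = unlist(lapply(led, `[[`, "e")),
    window = factor(unlist(lapply(led, `[[`, "w")),
                    levels = WINDOW_LEVELS),
    drug = unlist(lapply(led, `[[`, "d")),
    stringsAsFactors = FALSE)
  ledger$days <- ledger$end - ledger$start
  pat_row <- match(ledger$patient_id, ids)
  ledger$hazard <- cfg$baseline_hazard *
    as.numeric(cfg$window_rr[as.character(ledger$window)]) *
    cfg$modality_rr^(ledger$drug == "buprenorphine") *
    exp(log_rate_x[pat_row])

  ## --- outcome events ---------------------------------------------------
  lambda <- ledger$hazard * ledger$days / DAYS_PER_YEAR
  n_ev <- stats::rpois(nrow(ledger), lambda)
  ev_row <- rep(seq_len(nrow(ledger)), n_ev)
  ev_off <- floor(stats::runif(length(ev_row)) * ledger$days[ev_row])
  ev_pid <- ledger$patient_id[ev_row]
  ev_date <- index_date[match(ev_pid, ids)] +
    as.integer(ledger$start[ev_row] + ev_off)

  ## --- admissions table -------------------------------------------------
  n_out <- length(ev_pid)
  out_code <- sample(NONFATAL_OD_CODES, n_out, replace = TRUE)
  # a third of overdose diagnoses sit in a secondary position behind an
  # unrelated primary diagnosis, exercising any-position ascertainment
  secondary <- stats::runif(n_out) < 1 / 3

  n_noise <- stats::rpois(n, cfg$noise_admission_rate * fu_days /
                            DAYS_PER_YEAR)
  noise_pid <- rep(ids, n_noise)
  noise_date <- index_date[rep(seq_len(n), n_noise)] +
    floor(stats::runif(length(noise_pid)) *
            fu_days[rep(seq_len(n), n_noise)])

  hist_has <- if ("overdose_history" %in% colnames(X)) {
    X[, "overdose_history"] == 1L
  } else rep(FALSE, n)
  hist_pid <- ids[hist_has]
  hist_date <- index_date[hist_has] -
    sample(30:365, sum(hist_has), replace = TRUE)

  adm <- rbind(
    data.frame(patient_id = ev_pid, admission_date = ev_date,
               diagnosis_code = out_code,
               position = ifelse(secondary, 2L, 1L),
               stringsAsFactors = FALSE),
    if (n_out) data.frame(patient_id = ev_pid[secondary],
                          admission_date = ev_date[secondary],
                          diagnosis_code = sample(NOISE_ADM_CODES,
                                                  sum(secondary), TRUE),
                          position = rep(1L, sum(secondary)),
                          stringsAsFactors = FALSE),
    data.frame(patient_id = noise_pid, admission_date = noise_date,
               diagnosis_code = sample(NOISE_ADM_CODES,
                                       length(noise_pid), TRUE),
               position = rep(1L, length(noise_pid)),
               stringsAsFactors = FALSE),
    data.frame(patient_id = hist_pid, admission_date = hist_date,
               diagnosis_code = sample(NONFATAL_OD_CODES,
                                       length(hist_pid), TRUE),
               position = rep(1L, length(hist_pid)),
               stringsAsFactors = FALSE))
  # admission ids: one admission per (event or noise record); the
  # secondary-code rows above share the id of their parent admission
  adm_key <- c(seq_len(n_out),
               if (n_out) which(secondary),
               n_out + seq_len(length(noise_pid) + length(hist_pid)))
  adm$admission_id <- sprintf("A%07d", adm_key)
  adm <- adm[order(adm$patient_id, adm$admission_date,
                   adm$admission_id, adm$position),
             c("patient_id", "admission_id", "admission_date",
               "diagnosis_code", "position")]
  row.names(adm) <- NULL

  ## --- prescriptions table ----------------------------------------------
  rx <- data.frame(
    patient_id = unlist(rx_pid),
    issue_date = index_date[match(unlist(rx_pid), ids)] +
      as.integer(unlist(rx_day)),
    drug = unlist(rx_drug), stringsAsFactors = FALSE)
  rx$product_code <- ifelse(rx$drug == "methadone", "MET-ORAL-SOL",
                            "BUP-SL-8MG")
  analg <- which(stats::runif(n) < es$analgesia_rx_prob)
  if (length(analg)) {
    a_bup <- stats::runif(length(analg)) < 0.5
    rx <- rbind(rx, data.frame(
      patient_id = ids[analg],
      issue_date = reg_start[analg] +
        floor(stats::runif(length(analg)) *
                as.integer(reg_end[analg] - reg_start[analg])),
      drug = ifelse(a_bup, "buprenorphine", "methadone"),
      product_code = ifelse(a_bup, "BUP-PATCH-5", "MET-LINCTUS"),
      stringsAsFactors = FALSE))
  }
  rx <- rx[order(rx$patient_id, rx$issue_date), ]
  row.names(rx) <- NULL

  ## --- deaths and patients ----------------------------------------------
  deaths <- rbind(
    data.frame(patient_id = ids[died_od],
               death_date = index_date[died_od] + fu_days[died_od],
               cause_code = rep(FATAL_OD_CODE, sum(died_od)),
               stringsAsFactors = FALSE),
    data.frame(patient_id = ids[died_other],
               death_date = index_date[died_other] + fu_days[died_other],
               cause_code = rep(OTHER_DEATH_CODE, sum(died_other)),
               stringsAsFactors = FALSE))
  row.names(deaths) <- NULL

  patients <- data.frame(patient_id = ids, birth_year = birth_year,
                         gender = gender, region = region,
                         imd_quintile = imd, reg_start = reg_start,
                         reg_end = reg_end, stringsAsFactors = FALSE)
  for (j in seq_len(nconf)) patients[[colnames(X)[j]]] <- X[, j]

  ground_truth <- structure(list(
    params = list(baseline_hazard = cfg$baseline_hazard,
                  window_rr = cfg$window_rr,
                  modality_rr = cfg$modality_rr,
                  confounders = cfg$confounders,
                  assignment_intercept = cfg$assignment_intercept),
    follow_up = data.frame(patient_id = ids, index_date = index_date,
                           fu_days = fu_days, drug = drug0,
                           switch_day = switch_day,
                           died_overdose = died_od,
                           stringsAsFactors = FALSE),
    ledger = ledger,
    seed = cfg$seed), class = "oat_ground_truth")

  structure(list(patients = patients, prescriptions = rx,
                 admissions = adm, deaths = deaths,
                 ground_truth = ground_truth, config = cfg),
            class = "oat_cohort")
}

#' Expected event counts per risk-window stratum
#'
#' Analytic expectation hazard x person-time of the simulated event
#' process, aggregated per window (and modality), for use as a
#' simulation oracle.
#'
#' @param ground_truth the `ground_truth` element of a cohort from
#'   [generate_cohort()].
#' @param upto_switch truncate each switching patient's ledger at the
#'   switch day (the analysis censors there), default FALSE.
#' @param by stratification columns of the ledger, default
#'   `c("window", "drug")`.
#' @return data frame with the stratum columns, person_years and
#'   expected_events.
#' @export
expected_counts <- function(ground_truth, upto_switch = FALSE,
                            by = c("window", "drug")) {
  if (!inherits(ground_truth, "oat_ground_truth")) {
    stop("ground_truth must come from generate_cohort()", call. = FALSE)
  }
  led <- ground_truth$ledger
  if (upto_switch) {
    sw <- ground_truth$follow_up$switch_day[
      match(led$patient_id, ground_truth$follow_up$patient_id)]
    cap <- ifelse(is.na(sw), Inf, sw)
    led$end <- pmin(led$end, cap)
    led <- led[led$end > led$start, , drop = FALSE]
    led$days <- led$end - led$start
  }
  led$py <- led$days / DAYS_PER_YEAR
  led$expected <- led$hazard * led$py
  f <- stats::as.formula(paste("cbind(py, expected) ~",
                               paste(by, collapse = " + ")))
  agg <- stats::aggregate(f, data = led, FUN = sum, drop = TRUE)
  names(agg)[names(agg) == "py"] <- "person_years"
  names(agg)[names(agg) == "expected"] <- "expected_events"
  agg
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes patients.tsv, prescriptions.tsv, admissions.tsv and deaths.tsv
#' (tab-delimited, ISO-8601 dates) plus ground_truth.json.
#'
#' @param cohort an `oat_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "oat_cohort")) {
    stop("cohort must come from generate_cohort()", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("patients", "prescriptions", "admissions", "deaths")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(cohort[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  gt <- cohort$ground_truth
  gt_ser <- list(params = gt$params,
                 seed = gt$seed,
                 follow_up = transform(gt$follow_up,
                                       index_date = format(index_date)),
                 ledger = gt$ledger)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_ser, p, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, p))
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir directory containing the four .tsv tables.
#' @return list with patients, prescriptions, admissions, deaths (dates
#'   parsed).
#' @export
read_cohort <- function(dir) {
  rd <- function(nm, datecols) {
    df <- utils::read.delim(file.path(dir, paste0(nm, ".tsv")),
                            stringsAsFactors = FALSE)
    for (dc in intersect(datecols, names(df))) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  list(patients = rd("patients", c("reg_start", "reg_end")),
       prescriptions = rd("prescriptions", "issue_date"),
       admissions = rd("admissions", "admission_date"),
       deaths = rd("deaths", "death_date"))
}
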