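# Outcome and covariate-history ascertainment against clinical code lists.
#
# Hospital admissions (ICD-10 discharge diagnoses), death registrations
# (cause-of-death codes) and primary-care history records are classified
# into dated overdose events purely by membership of configurable code
# lists; no clinical logic is hard-wired.

CODE_SYSTEMS <- c("ICD10", "READ", "SNOMED", "PRODUCT")

#' Read a clinical code list from CSV
#'
#' The file must have a header with columns `code`, `system`, `category`.
#' `system` is one of ICD10, READ, SNOMED, PRODUCT. Typical categories are
#' `nonfatal_overdose`, `fatal_overdose`, `overdose_history`,
#' `self_harm_history` and `analgesia_exclusion`, but any label is allowed.
#'
#' @param path path to a CSV file.
#' @return data frame of class `code_list` with columns code, system,
#'   category.
#' @export
read_code_list <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  code_list(cl)
}

#' Construct a code list from a data frame
#'
#' @param df data frame with columns code, system, category.
#' @return the validated data frame with class `code_list` prepended.
#' @export
code_list <- function(df) {
  assert_columns(df, c("code", "system", "category"), "code list")
  bad <- setdiff(unique(df$system), CODE_SYSTEMS)
  if (length(bad)) {
    stop(sprintf("unknown coding system(s): %s (expected one of %s)",
                 paste(bad, collapse = ", "),
                 paste(CODE_SYSTEMS, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(df[c("system", "category", "code")])
  if (any(dup)) {
    stop(sprintf("duplicated code(s) within (system, category): %s",
                 paste(unique(df$code[dup]), collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("code_list", class(df))
  df
}

# ICD-10 codes are compared without dots or spaces, case-insensitively,
# so "T40.1" in the data matches list entry "T40" under prefix matching.
normalise_code <- function(x) toupper(gsub("[. ]", "", x))

codes_for <- function(code_list, category, system = NULL) {
  sel <- code_list$category == category
  if (!is.null(system)) sel <- sel & code_list$system == system
  code_list$code[sel]
}

match_codes <- function(codes, list_codes, matching = c("prefix", "exact")) {
  matching <- match.arg(matching)
  codes <- normalise_code(codes)
  list_codes <- normalise_code(list_codes)
  if (!length(list_codes)) return(rep(FALSE, length(codes)))
  if (matching == "exact") return(codes %in% list_codes)
  hit <- rep(FALSE, length(codes))
  for (p in unique(list_codes)) hit <- hit | startsWith(codes, p)
  hit
}

#' Classify hospital admissions as non-fatal overdose events
#'
#' An admission (identified by `admission_id`) contributes exactly one
#' event when at least one of its discharge diagnosis codes, in any
#' counted position, matches the non-fatal overdose code list. Admissions
#' with several matching codes are not double counted. Events are dated
#' at the admission date.
#'
#' @param admissions data frame with one row per recorded diagnosis:
#'   columns patient_id, admission_id, admission_date, diagnosis_code,
#'   position (1 = primary).
#' @param code_list a [code_list()]; entries with `system == "ICD10"` and
#'   the requested category are used.
#' @param matching `"prefix"` (default; T40 matches T40.1) or `"exact"`.
#' @param positions `"any"` (default) to count all diagnosis positions, or
#'   `"primary"` to restrict to position 1.
#' @param category code-list category to match, default
#'   `"nonfatal_overdose"`.
#' @return data frame of events: patient_id, event_date, kind
#'   (`"nonfatal"`), source_id (the admission id).
#' @export
classify_admissions <- function(admissions, code_list,
                                matching = c("prefix", "exact"),
                                positions = c("any", "primary"),
                                category = "nonfatal_overdose") {
  matching <- match.arg(matching)
  positions <- match.arg(positions)
  assert_columns(admissions,
                 c("patient_id", "admission_id", "admission_date",
                   "diagnosis_code"), "admissions")
  if (!inherits(code_list, "code_list")) code_list <- code_list(code_list)
  adm <- admissions
  if (positions == "primary") {
    assert_columns(adm, "position", "admissions")
    adm <- adm[adm$position == 1L, , drop = FALSE]
  }
  if (!nrow(adm)) {
    return(empty_events())
  }
  hit <- match_codes(adm$diagnosis_code,
                     codes_for(code_list, category, "ICD10"), matching)
  adm <- adm[hit, , drop = FALSE]
  adm <- adm[!duplicated(adm$admission_id), , drop = FALSE]
  data.frame(patient_id = adm$patient_id,
             event_date = as_date(adm$admission_date),
             kind = rep("nonfatal", nrow(adm)),
             source_id = as.character(adm$admission_id),
             stringsAsFactors = FALSE)
}

#' Classify deaths as fatal overdose (drug poisoning) events
#'
#' One event per deceased patient whose registered causes of death include
#' at least one code in the fatal-overdose (drug poisoning) list. Events
#' are dated at the death date. Any downstream mortality-censoring window
#' is applied in person-time handling, not here.
#'
#' @param deaths data frame with one row per recorded cause: columns
#'   patient_id, death_date, cause_code.
#' @param code_list a [code_list()].
#' @param matching `"prefix"` or `"exact"`.
#' @param category code-list category, default `"fatal_overdose"`.
#' @return data frame of events: patient_id, event_date, kind (`"fatal"`),
#'   source_id (the patient id).
#' @export
classify_deaths <- function(deaths, code_list,
                            matching = c("prefix", "exact"),
                            category = "fatal_overdose") {
  matching <- match.arg(matching)
  if (is.null(deaths) || !nrow(deaths)) return(empty_events())
  assert_columns(deaths, c("patient_id", "death_date", "cause_code"),
                 "deaths")
  if (!inherits(code_list, "code_list")) code_list <- code_list(code_list)
  hit <- match_codes(deaths$cause_code,
                     codes_for(code_list, category, "ICD10"), matching)
  d <- deaths[hit, , drop = FALSE]
  d <- d[!duplicated(d$patient_id), , drop = FALSE]
  data.frame(patient_id = d$patient_id,
             event_date = as_date(d$death_date),
             kind = rep("fatal", nrow(d)),
             source_id = as.character(d$patient_id),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(patient_id = character(), event_date = as.Date(character()),
             kind = character(), source_id = character(),
             stringsAsFactors = FALSE)
}

#' Flag pre-index history of an outcome per patient
#'
#' Returns TRUE for a patient iff at least one supplied event falls
#' strictly before that patient's index date and within the lookback.
#' An event on the index date itself does not count.
#'
#' @param events data frame with columns patient_id, event_date (already
#'   classified against the relevant history code list).
#' @param index_dates data frame with columns patient_id, index_date.
#' @param lookback_years lookback length in years, or `Inf` (default) for
#'   all available history.
#' @return data frame with columns patient_id, flag (logical), one row per
#'   patient in `index_dates`.
#' @export
flag_history <- function(events, index_dates, lookback_years = Inf) {
  assert_columns(index_dates, c("patient_id", "index_date"), "index dates")
  flag <- rep(FALSE, nrow(index_dates))
  if (!is.null(events) && nrow(events)) {
    assert_columns(events, c("patient_id", "event_date"), "events")
    idx <- as_date(index_dates$index_date)[
      match(events$patient_id, index_dates$patient_id)]
    d <- as.numeric(idx - as_date(events$event_date))
    ok <- !is.na(d) & d > 0
    if (is.finite(lookback_years)) {
      ok <- ok & d <= lookback_years * DAYS_PER_YEAR
    }
    flag <- index_dates$patient_id %in% events$patient_id[ok]
  }
  data.frame(patient_id = index_dates$patient_id, flag = flag,
             stringsAsFactors = FALSE)
}
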