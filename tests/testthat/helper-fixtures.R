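# Small in-code fixtures shared across test files.

EPOCH <- as.Date("2000-01-01")

day <- function(d) EPOCH + d

# prescriptions for one patient given issue-day offsets
rx_days <- function(days, id = "p1", drug = "methadone",
                    product = "MET-ORAL-SOL") {
  data.frame(patient_id = id, issue_date = day(days), drug = drug,
             product_code = product, stringsAsFactors = FALSE)
}

fu_spec <- function(id = "p1", index = 0, end = 365) {
  data.frame(patient_id = id, index_date = day(index),
             observation_end = day(end), stringsAsFactors = FALSE)
}

episodes_df <- function(id, starts, ends, drug = "methadone") {
  data.frame(patient_id = id, drug = drug, start = day(starts),
             end = day(ends), n_rx = 1L, stringsAsFactors = FALSE)
}

toy_code_list <- function() {
  code_list(data.frame(
    code = c("T40", "T43.6", "X42", "BUP-PATCH-5", "MET-LINCTUS"),
    system = c("ICD10", "ICD10", "ICD10", "PRODUCT", "PRODUCT"),
    category = c("nonfatal_overdose", "nonfatal_overdose",
                 "fatal_overdose", "analgesia_exclusion",
                 "analgesia_exclusion"),
    stringsAsFactors = FALSE))
}

admission <- function(id, adm_id, d, codes, positions = seq_along(codes)) {
  data.frame(patient_id = id, admission_id = adm_id,
             admission_date = day(d), diagnosis_code = codes,
             position = positions, stringsAsFactors = FALSE)
}

# minimal hand-built ground-truth object for expected_counts tests
gt_manual <- function(ledger) {
  structure(list(params = list(), ledger = ledger,
                 follow_up = data.frame(
                   patient_id = unique(ledger$patient_id),
                   switch_day = NA_integer_,
                   stringsAsFactors = FALSE)),
            class = "oat_ground_truth")
}

# a zero-effect confounder table (no confounding)
no_confounding <- function() {
  data.frame(name = character(0), prevalence = numeric(0),
             assign_log_odds = numeric(0), rate_log_rr = numeric(0),
             stringsAsFactors = FALSE)
}
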