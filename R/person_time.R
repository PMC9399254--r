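# Person-time splitting into risk windows, event attribution and
# stratum aggregation.
#
# Follow-up is tiled, without gaps or overlap, by half-open intervals
# labelled with one of four risk windows: weeks 1-4 of a treatment
# episode (`in_1_4`), the remainder of the episode (`in_gt4`), weeks 1-4
# after episode end (`out_1_4`) and the remainder of the out-of-treatment
# period (`out_gt4`). Windows restart at every episode transition.

#' Split follow-up into labelled risk intervals
#'
#' Each in-treatment episode contributes its first `window_days` days as
#' `in_1_4` (truncated at the episode end) and the remainder as `in_gt4`;
#' each out-of-treatment period contributes its first `window_days` days
#' as `out_1_4` and the remainder as `out_gt4`. Windows restart at every
#' episode start and end unless `restart_windows = FALSE`, in which case
#' only the first initiation and first cessation carry 1-4 week windows.
#' All intervals are truncated to `[index_date, observation_end)`.
#' Out-of-treatment intervals carry the modality of the episode that
#' preceded them.
#'
#' If `patients` (with `birth_year`) is supplied, intervals are further
#' split at band-changing birthdays and labelled with a time-varying age
#' band (18-24, 25-34, 35-44, 45-64).
#'
#' @param episodes disjoint episodes from [build_episodes()].
#' @param follow_up spec from [make_follow_up()] (possibly transformed by
#'   [apply_censor_variants()]).
#' @param window_days length of the elevated-risk window, default 28
#'   (four weeks).
#' @param restart_windows restart 1-4 week windows at every transition
#'   (default TRUE).
#' @param patients optional patients table for age-band splitting.
#' @return data frame of risk intervals: patient_id, start, end (Dates,
#'   half-open), days, window (factor), drug, and age_band when
#'   `patients` is given. Per patient the intervals exactly tile
#'   `[index_date, observation_end)`.
#' @export
split_follow_up <- function(episodes, follow_up, window_days = 28,
                            restart_windows = TRUE, patients = NULL) {
  assert_columns(follow_up, c("patient_id", "index_date",
                              "observation_end"), "follow_up")
  ep <- episodes
  ep$start <- as_date(ep$start); ep$end <- as_date(ep$end)
  fu <- follow_up
  fu$index_date <- as_date(fu$index_date)
  fu$observation_end <- as_date(fu$observation_end)

  ep_by_pat <- split(ep[c("start", "end", "drug")], ep$patient_id)

  res_pid <- list(); res_s <- list(); res_e <- list()
  res_w <- list(); res_d <- list()
  k <- 0L
  for (j in seq_len(nrow(fu))) {
    pid <- fu$patient_id[j]
    idx <- as.integer(fu$index_date[j])
    oe <- as.integer(fu$observation_end[j])
    e <- ep_by_pat[[pid]]
    segs_s <- integer(0); segs_e <- integer(0)
    segw <- character(0); segd <- character(0)
    if (!is.null(e) && nrow(e)) {
      es <- as.integer(e$start); ee <- as.integer(e$end)
      if (is.unsorted(es)) {
        o <- order(es); es <- es[o]; ee <- ee[o]
        e <- e[o, , drop = FALSE]
      }
      if (any(es[-1] < ee[-length(ee)])) {
        stop(sprintf("overlapping episodes for patient %s", pid),
             call. = FALSE)
      }
      add <- function(s0, e0, anchor, side, drug, first_transition) {
        s0 <- max(s0, idx); e0 <- min(e0, oe)
        if (e0 <= s0) return(invisible())
        cut <- anchor + window_days
        early <- if (restart_windows || first_transition) {
          min(max(cut, s0), e0)
        } else s0
        if (early > s0) {
          k <<- k + 1L
          res_pid[[k]] <<- pid; res_s[[k]] <<- s0; res_e[[k]] <<- early
          res_w[[k]] <<- paste0(side, "_1_4"); res_d[[k]] <<- drug
        }
        if (e0 > early) {
          k <<- k + 1L
          res_pid[[k]] <<- pid; res_s[[k]] <<- early; res_e[[k]] <<- e0
          res_w[[k]] <<- paste0(side, "_gt4"); res_d[[k]] <<- drug
        }
      }
      cur <- idx
      for (i in seq_along(es)) {
        if (es[i] >= oe) break
        if (es[i] > cur) {
          # out-of-treatment period before this episode, anchored at the
          # previous episode's end (cessation date)
          add(cur, es[i], cur, "out",
              drug = if (i > 1L) e$drug[i - 1L] else e$drug[i],
              first_transition = i == 2L)
        }
        add(es[i], ee[i], es[i], "in", drug = e$drug[i],
            first_transition = i == 1L)
        cur <- ee[i]
      }
      if (cur < oe) {
        last_i <- max(which(es < oe))
        add(cur, oe, cur, "out", drug = e$drug[last_i],
            first_transition = last_i == 1L)
      }
    } else {
      # no episodes within follow-up: whole span is out of treatment
      add_s <- idx; cut <- min(idx + window_days, oe)
      if (cut > add_s) {
        k <- k + 1L
        res_pid[[k]] <- pid; res_s[[k]] <- add_s; res_e[[k]] <- cut
        res_w[[k]] <- "out_1_4"; res_d[[k]] <- NA_character_
      }
      if (oe > cut) {
        k <- k + 1L
        res_pid[[k]] <- pid; res_s[[k]] <- cut; res_e[[k]] <- oe
        res_w[[k]] <- "out_gt4"; res_d[[k]] <- NA_character_
      }
    }
  }
  iv <- data.frame(patient_id = unlist(res_pid) %||% character(0),
                   start = as.Date(unlist(res_s) %||% integer(0),
                                   origin = "1970-01-01"),
                   end = as.Date(unlist(res_e) %||% integer(0),
                                 origin = "1970-01-01"),
                   window = factor(unlist(res_w) %||% character(0),
                                   levels = WINDOW_LEVELS),
                   drug = unlist(res_d) %||% character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(patients)) iv <- add_age_bands(iv, patients)
  iv$days <- as.numeric(iv$end - iv$start)
  iv
}

# Split intervals at band-changing birthdays and label the age band
# current at each interval's start.
add_age_bands <- function(intervals, patients) {
  assert_columns(patients, c("patient_id", "birth_year"), "patients")
  by <- patients$birth_year[match(intervals$patient_id,
                                  patients$patient_id)]
  s <- as.integer(as_date(intervals$start))
  e <- as.integer(as_date(intervals$end))
  # integer day numbers of the band-changing birthdays (Jan 1 convention)
  yrs <- outer(by, AGE_BAND_BREAKS[-1], "+")
  need <- sort(unique(as.vector(yrs)))
  day_of <- as.integer(as.Date(paste0(need, "-01-01")))
  names(day_of) <- need
  cutm <- matrix(day_of[as.character(yrs)], nrow = nrow(intervals))
  inside <- cutm > s & cutm < e
  plain <- !rowSums(inside)
  pieces <- c(list(cbind(row = which(plain), s = s[plain], e = e[plain])),
              lapply(which(!plain), function(i) {
                b <- c(s[i], cutm[i, inside[i, ]], e[i])
                cbind(row = i, s = b[-length(b)], e = b[-1])
              }))
  m <- do.call(rbind, pieces)
  m <- m[order(m[, "row"], m[, "s"]), , drop = FALSE]
  out <- intervals[m[, "row"], , drop = FALSE]
  out$start <- as.Date(m[, "s"], origin = "1970-01-01")
  out$end <- as.Date(m[, "e"], origin = "1970-01-01")
  out$age_band <- age_band(age_at(out$start,
                                  by[m[, "row"]]))
  row.names(out) <- NULL
  out
}

#' Attribute overdose events to risk intervals
#'
#' Each event is assigned to the unique interval containing its date
#' (half-open containment: an event on an interval's end date belongs to
#' the next interval). Events falling outside every interval of their
#' patient — for example after the censoring date — are dropped with a
#' warning. With `first_event_only = TRUE` the per-patient interval set
#' is truncated the day after the first event, yielding the
#' time-to-first-event view used for hazard ratios.
#'
#' @param intervals risk intervals from [split_follow_up()].
#' @param events data frame with columns patient_id, event_date.
#' @param first_event_only censor each patient at the first event
#'   (default FALSE keeps all events).
#' @return the intervals with an integer `events` column; attribute
#'   `n_dropped` counts unattributable events.
#' @export
attribute_events <- function(intervals, events, first_event_only = FALSE) {
  iv <- intervals
  iv$events <- 0L
  if (is.null(events) || !nrow(events)) {
    attr(iv, "n_dropped") <- 0L
    return(iv)
  }
  assert_columns(events, c("patient_id", "event_date"), "events")
  ev <- events
  ev$day <- as.integer(as_date(ev$event_date))
  s <- as.integer(as_date(iv$start)); e <- as.integer(as_date(iv$end))

  idx_by_pat <- split(seq_len(nrow(iv)), iv$patient_id)
  hit <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    jj <- idx_by_pat[[ev$patient_id[i]]]
    j <- jj[s[jj] <= ev$day[i] & ev$day[i] < e[jj]]
    hit[i] <- if (length(j) == 1L) j else NA_integer_
  }
  dropped <- sum(is.na(hit))
  if (dropped) {
    warning(sprintf("%d event(s) outside follow-up intervals dropped",
                    dropped))
  }
  ok <- !is.na(hit)
  if (!first_event_only) {
    tab <- table(hit[ok])
    iv$events[as.integer(names(tab))] <- as.integer(tab)
    attr(iv, "n_dropped") <- dropped
    return(iv)
  }
  # first-event view: truncate follow-up the day after the first event
  first_day <- tapply(ev$day[ok], ev$patient_id[ok], min)
  fd <- as.integer(first_day[match(iv$patient_id, names(first_day))])
  keep <- is.na(fd) | s <= fd
  iv <- iv[keep, , drop = FALSE]
  s <- s[keep]; e <- e[keep]; fd <- fd[keep]
  contains <- !is.na(fd) & s <= fd & fd < e
  iv$end[contains] <- as.Date(fd[contains] + 1L, origin = "1970-01-01")
  iv$events[contains] <- 1L
  iv$days <- as.numeric(as_date(iv$end) - as_date(iv$start))
  row.names(iv) <- NULL
  attr(iv, "n_dropped") <- dropped
  iv
}

#' Aggregate events and person-time by stratum
#'
#' @param intervals attributed intervals from [attribute_events()].
#' @param by character vector of stratification columns, default
#'   `"window"`; use e.g. `c("window", "drug")` for modality-specific
#'   rates.
#' @return data frame with the stratum columns plus person_years, events
#'   and rate_per_100py (= 100 x events / person-years; 365.25 days per
#'   year).
#' @export
aggregate_person_time <- function(intervals, by = "window") {
  assert_columns(intervals, c(by, "days", "events"), "intervals")
  f <- stats::as.formula(paste("cbind(days, events) ~",
                               paste(by, collapse = " + ")))
  agg <- stats::aggregate(f, data = intervals, FUN = sum, drop = TRUE)
  agg$person_years <- agg$days / DAYS_PER_YEAR
  agg$rate_per_100py <- 100 * agg$events / agg$person_years
  agg$days <- NULL
  agg
}

#' Apply a follow-up censoring variant
#'
#' `"one_year_post_treatment"` shortens observation to one year (365
#' days) after the end of the patient's last treatment episode;
#' `"max_followup_years"` restricts follow-up to `years` after index
#' (the default 10 years mirrors restricting long observation periods to
#' stabilise model fitting). Observation is never lengthened.
#'
#' @param follow_up spec from [make_follow_up()].
#' @param episodes episodes, required for the one-year variant.
#' @param variant one of `"none"`, `"one_year_post_treatment"`,
#'   `"max_followup_years"`.
#' @param years horizon for `max_followup_years`, default 10.
#' @return the follow-up spec with (possibly) shortened observation_end.
#' @export
apply_censor_variants <- function(follow_up, episodes = NULL,
                                  variant = c("none",
                                              "one_year_post_treatment",
                                              "max_followup_years"),
                                  years = 10) {
  variant <- match.arg(variant)
  fu <- follow_up
  fu$index_date <- as_date(fu$index_date)
  fu$observation_end <- as_date(fu$observation_end)
  if (variant == "none") return(fu)
  if (variant == "one_year_post_treatment") {
    if (is.null(episodes)) stop("episodes required for this variant",
                                call. = FALSE)
    last_end <- tapply(as.integer(as_date(episodes$end)),
                       episodes$patient_id, max)
    cap <- as.Date(as.integer(last_end[match(fu$patient_id,
                                             names(last_end))]) + 365L,
                   origin = "1970-01-01")
    fu$observation_end <- pmin(fu$observation_end, cap, na.rm = TRUE)
  } else {
    cap <- fu$index_date + round(years * DAYS_PER_YEAR)
    fu$observation_end <- pmin(fu$observation_end, cap)
  }
  fu$observation_end <- pmax(fu$observation_end, fu$index_date)
  fu
}
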