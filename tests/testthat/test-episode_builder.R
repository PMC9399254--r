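test_that("gap rule splits and joins episodes as specified", {
  # gap = 40 - 14 = 26 >= 14: two episodes with an out period between
  eps <- build_episodes(rx_days(c(0, 40)))
  expect_equal(nrow(eps), 2L)
  expect_equal(as.integer(eps$start - EPOCH), c(0L, 40L))
  expect_equal(as.integer(eps$end - EPOCH), c(14L, 54L))
  # gap = 20 - 14 = 6 < 14: one episode [0, 34)
  eps2 <- build_episodes(rx_days(c(0, 20)))
  expect_equal(nrow(eps2), 1L)
  expect_equal(as.integer(eps2$end - EPOCH), 34L)
  expect_equal(eps2$n_rx, 2L)
  # boundary: gap of exactly max_gap_days breaks the episode
  expect_equal(nrow(build_episodes(rx_days(c(0, 28)))), 2L)
  expect_equal(nrow(build_episodes(rx_days(c(0, 27)))), 1L)
  # single prescription covers exactly the supply duration
  eps3 <- build_episodes(rx_days(0))
  expect_equal(as.integer(eps3$end - eps3$start), 14L)
})

test_that("overlapping prescriptions extend or stack the expiry", {
  # overlap at day 7: extend mode ends at 7 + 14 = 21
  e_ext <- build_episodes(rx_days(c(0, 7)), overlap_mode = "extend")
  expect_equal(as.integer(e_ext$end - EPOCH), 21L)
  # stack mode adds a full supply to the running expiry: 14 + 14 = 28
  e_stk <- build_episodes(rx_days(c(0, 7)), overlap_mode = "stack")
  expect_equal(as.integer(e_stk$end - EPOCH), 28L)
  # extend never shortens: a same-day duplicate leaves expiry unchanged
  e_dup <- build_episodes(rx_days(c(0, 0, 5)), overlap_mode = "extend")
  expect_equal(as.integer(e_dup$end - EPOCH), 19L)
})

test_that("episode construction is invariant to duplicated rows", {
  rx <- rx_days(c(0, 20, 40, 60))
  expect_equal(build_episodes(rx), build_episodes(rbind(rx, rx[2, ])))
})

test_that("shorter supply gives earlier episode ends; larger gaps give fewer episodes", {
  set.seed(11)
  for (r in 1:20) {
    days <- sort(sample(0:250, 12))
    rx <- rx_days(days)
    e14 <- build_episodes(rx, supply_days = 14)
    e7 <- build_episodes(rx, supply_days = 7)
    # each 7-day episode ends no later than the 14-day episode covering
    # its start
    for (i in seq_len(nrow(e7))) {
      j <- max(which(as.integer(e14$start) <= as.integer(e7$start[i])))
      expect_lte(as.integer(e7$end[i]), as.integer(e14$end[j]))
    }
    n_eps <- vapply(c(7, 14, 21), function(g) {
      nrow(build_episodes(rx, max_gap_days = g))
    }, 0L)
    expect_true(all(diff(n_eps) <= 0))
  }
})

test_that("switch censoring keeps the first drug and records the switch", {
  rx <- rbind(rx_days(c(0, 20), drug = "methadone"),
              rx_days(50, drug = "buprenorphine",
                      product = "BUP-SL-8MG"))
  out <- censor_at_switch(rx)
  expect_equal(unique(out$prescriptions$drug), "methadone")
  expect_equal(nrow(out$prescriptions), 2L)
  expect_equal(out$switches$switch_date, day(50))
  expect_equal(nrow(out$excluded), 0L)
  # single-drug patient passes through untouched
  one <- censor_at_switch(rx_days(c(0, 20)))
  expect_equal(nrow(one$prescriptions), 2L)
  expect_equal(nrow(one$switches), 0L)
})

test_that("patients starting both drugs on the index date are excluded", {
  rx <- rbind(rx_days(0, drug = "methadone"),
              rx_days(c(0, 10), drug = "buprenorphine",
                      product = "BUP-SL-8MG"))
  out <- censor_at_switch(rx)
  expect_equal(out$excluded$patient_id, "p1")
  expect_equal(out$excluded$reason, "modality_tie")
  expect_equal(nrow(out$prescriptions), 0L)
})

test_that("analgesia-formulation exclusions are removed, others retained", {
  cl <- toy_code_list()
  rx <- rbind(rx_days(0, product = "MET-ORAL-SOL"),
              rx_days(5, product = "MET-LINCTUS"),
              rx_days(9, id = "p2", drug = "buprenorphine",
                      product = "BUP-PATCH-5"))
  out <- clean_prescriptions(rx, cl)
  expect_equal(nrow(out), 1L)
  expect_equal(out$product_code, "MET-ORAL-SOL")
  expect_equal(attr(out, "n_removed"), 2L)
  # empty exclusion list leaves the input unchanged
  out2 <- clean_prescriptions(rx, NULL)
  expect_equal(nrow(out2), 3L)
})

test_that("follow-up spec enforces age, registration, and censoring", {
  pat <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4"),
    birth_year = c(1970, 1990, 1970, 1970),  # p2 is 10 at index
    reg_start = day(c(-400, -400, -10, -400)),  # p3 registered late
    reg_end = day(c(1000, 1000, 1000, 1000)))
  rx <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(id) {
    rx_days(0, id = id)
  }))
  deaths <- data.frame(patient_id = "p4", death_date = day(100),
                       cause_code = "X42")
  res <- make_follow_up(pat, rx, study_start = EPOCH,
                        study_end = day(5000), deaths = deaths)
  expect_setequal(res$follow_up$patient_id, c("p1", "p4"))
  expect_equal(res$audit$reason[res$audit$patient_id == "p2"],
               "age_out_of_range")
  expect_equal(res$audit$reason[res$audit$patient_id == "p3"],
               "insufficient_registration")
  # death censors follow-up
  expect_equal(res$follow_up$observation_end[
    res$follow_up$patient_id == "p4"], day(100))
  expect_equal(res$follow_up$observation_end[
    res$follow_up$patient_id == "p1"], day(1000))
})

test_that("episode summaries band durations with 30.44-day months", {
  eps <- episodes_df("p1", c(0, 100), c(14, 180))  # 14 and 80 days
  fu <- fu_spec(end = 365)
  s <- episode_summaries(eps, fu)
  bands <- s$bands[s$bands$n > 0, ]
  expect_setequal(bands$band, c("up to 1 month", "1-3 months"))
  expect_equal(s$by_modality$n_episodes, 2L)
  expect_equal(s$by_modality$days_in_median, 94)  # 14 + 80 observed days
  empty <- episode_summaries(eps[0, ], fu)
  expect_equal(nrow(empty$bands), 0L)
})
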