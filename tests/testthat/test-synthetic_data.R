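test_that("configuration invariants are validated with named errors", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(baseline_hazard = -1), "baseline_hazard")
  expect_error(sim_config(window_rr = c(in_1_4 = 5, in_gt4 = 1,
                                        out_1_4 = 13)), "window_rr")
  expect_error(sim_config(window_rr = c(in_1_4 = 5, in_gt4 = 2,
                                        out_1_4 = 13, out_gt4 = 1.4)),
               "reference")
  expect_error(sim_config(modality_rr = 0), "modality_rr")
  expect_error(sim_config(episode_spec = list(switch_prob = 2)),
               "switch_prob")
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_patients = 120, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (nm in c("patients", "prescriptions", "admissions", "deaths")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  expect_identical(a$ground_truth$ledger, b$ground_truth$ledger)
  c2 <- generate_cohort(sim_config(n_patients = 120, seed = 100))
  expect_false(identical(a$prescriptions, c2$prescriptions))
})

test_that("the latent ledger tiles follow-up and stays inside it", {
  co <- generate_cohort(sim_config(n_patients = 300, seed = 5))
  led <- co$ground_truth$ledger
  fu <- co$ground_truth$follow_up
  expect_true(all(led$end > led$start))
  tot <- tapply(led$days, led$patient_id, sum)
  expect_equal(as.numeric(tot[fu$patient_id]), as.numeric(fu$fu_days))
  expect_true(all(led$start >= 0))
  expect_true(all(led$end <= fu$fu_days[match(led$patient_id,
                                              fu$patient_id)]))
  # every outcome event lies within its patient's follow-up
  cl <- oat_default_code_lists()
  ev <- classify_admissions(co$admissions, cl)
  idx <- fu$index_date[match(ev$patient_id, fu$patient_id)]
  post <- ev[ev$event_date >= idx, ]
  fud <- fu$fu_days[match(post$patient_id, fu$patient_id)]
  expect_true(all(as.numeric(post$event_date - idx[ev$event_date >= idx])
                  < fud))
})

test_that("prescription cascades reconstruct to the latent episodes", {
  co <- generate_cohort(sim_config(n_patients = 200, seed = 8))
  cl <- oat_default_code_lists()
  rx <- clean_prescriptions(co$prescriptions, cl)
  sw <- censor_at_switch(rx)
  eps <- build_episodes(sw$prescriptions)
  led <- co$ground_truth$ledger
  fu <- co$ground_truth$follow_up
  # non-switching patients: episode-day totals agree with the ledger's
  # in-treatment days (ledger truncates at follow-up end)
  ns <- fu$patient_id[is.na(fu$switch_day)]
  led_in <- led[led$patient_id %in% ns &
                  led$window %in% c("in_1_4", "in_gt4"), ]
  in_led <- tapply(led_in$days, led_in$patient_id, sum)
  e <- eps[eps$patient_id %in% ns, ]
  idx <- fu$index_date[match(e$patient_id, fu$patient_id)]
  end_cap <- idx + fu$fu_days[match(e$patient_id, fu$patient_id)]
  e$obs <- pmax(0, as.numeric(pmin(e$end, end_cap) - e$start))
  in_built <- tapply(e$obs, e$patient_id, sum)
  shared <- intersect(names(in_led), names(in_built))
  expect_gt(length(shared), 100)
  expect_equal(unname(in_built[shared]), unname(in_led[shared]))
})

test_that("a homogeneous process reproduces the baseline rate", {
  cfg <- sim_config(n_patients = 2000, seed = 21, baseline_hazard = 0.2,
                    window_rr = c(in_1_4 = 1, in_gt4 = 1, out_1_4 = 1,
                                  out_gt4 = 1),
                    modality_rr = 1, confounders = no_confounding())
  co <- generate_cohort(cfg)
  gt <- co$ground_truth
  py <- sum(gt$ledger$days) / 365.25
  expected <- 0.2 * py
  cl <- oat_default_code_lists()
  ev <- classify_admissions(co$admissions, cl)
  idx <- gt$follow_up$index_date[match(ev$patient_id,
                                       gt$follow_up$patient_id)]
  observed <- sum(ev$event_date >= idx)
  # Poisson: observed within 3 Monte-Carlo standard errors
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
  rate <- 100 * observed / py
  expect_lt(abs(rate - 20), 3 * 100 * sqrt(expected) / py)
})

test_that("expected counts follow hazard x person-time and add up", {
  led <- data.frame(patient_id = "p1", start = 0, end = 28,
                    window = factor("in_1_4", c("in_1_4", "in_gt4",
                                                "out_1_4", "out_gt4")),
                    drug = "methadone", days = 28, hazard = 0.1)
  ec <- expected_counts(gt_manual(led))
  expect_equal(ec$expected_events, 0.1 * 28 / 365.25)
  # additivity across strata
  co <- generate_cohort(sim_config(n_patients = 150, seed = 13))
  gt <- co$ground_truth
  ec2 <- expected_counts(gt)
  expect_equal(sum(ec2$expected_events),
               sum(gt$ledger$hazard * gt$ledger$days / 365.25))
  expect_equal(sum(ec2$person_years), sum(gt$ledger$days) / 365.25)
})

test_that("expected counts match observed means over replicate seeds", {
  base <- sim_config(n_patients = 40, seed = 1)
  exp_tot <- NULL
  obs <- numeric(200)
  for (r in seq_len(200)) {
    co <- generate_cohort(sim_config(n_patients = 40, seed = 1000 + r))
    gt <- co$ground_truth
    ec <- expected_counts(gt, by = "window")
    if (r == 1) exp_tot <- 0
    exp_tot <- exp_tot + sum(ec$expected_events)
    cl <- oat_default_code_lists()
    ev <- classify_admissions(co$admissions, cl)
    idx <- gt$follow_up$index_date[match(ev$patient_id,
                                         gt$follow_up$patient_id)]
    obs[r] <- sum(ev$event_date >= idx)
  }
  mean_exp <- exp_tot / 200
  se <- sd(obs) / sqrt(200)
  expect_lt(abs(mean(obs) - mean_exp), 3 * se)
})

test_that("without confounding the crude modality ratio recovers the truth", {
  co <- generate_cohort(sim_config(n_patients = 5000, seed = 3,
                                   confounders = no_confounding()))
  gt <- co$ground_truth
  cl <- oat_default_code_lists()
  ev <- classify_admissions(co$admissions, cl)
  fu <- gt$follow_up
  idx <- fu$index_date[match(ev$patient_id, fu$patient_id)]
  ev <- ev[ev$event_date >= idx, ]
  # modality at event time from the ledger (patients can switch)
  led <- gt$ledger
  py <- tapply(led$days, led$drug, sum) / 365.25
  off <- as.numeric(ev$event_date -
                      fu$index_date[match(ev$patient_id, fu$patient_id)])
  led_pat <- split(led, led$patient_id)
  ev_drug <- vapply(seq_len(nrow(ev)), function(i) {
    l <- led_pat[[ev$patient_id[i]]]
    l$drug[which(l$start <= off[i] & off[i] < l$end)[1]]
  }, "")
  n_ev <- table(ev_drug)
  rr <- crude_rate_ratio(n_ev[["buprenorphine"]], py[["buprenorphine"]],
                         n_ev[["methadone"]], py[["methadone"]])
  expect_gt(0.4, rr$conf_low)
  expect_lt(0.4, rr$conf_high)
})

test_that("cohorts round-trip through delimited text and JSON", {
  co <- generate_cohort(sim_config(n_patients = 30, seed = 4))
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  expect_true(all(file.exists(file.path(
    d, c("patients.tsv", "prescriptions.tsv", "admissions.tsv",
         "deaths.tsv", "ground_truth.json")))))
  back <- read_cohort(d)
  expect_equal(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$prescriptions$issue_date, co$prescriptions$issue_date)
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$params$modality_rr, 0.4)
})
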