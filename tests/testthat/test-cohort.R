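w <- study_windows()
cm <- code_map()

test_that("index assignment picks the earliest qualifying DMT fill", {
  fills <- data.frame(
    patient_id = c("p1", "p2", "p2", "p3"),
    date = as.Date(c("2013-05-01", "2014-02-01", "2013-06-01", "2012-11-01")),
    code = c("DMT_DMF", "DMT_DMF", "DMT_TER", "DMT_DMF"),
    days_supply = 30L, stringsAsFactors = FALSE)
  idx <- assign_index(fills, w, cm)
  expect_equal(idx$index_date[idx$patient_id == "p1"], as.Date("2013-05-01"))
  expect_equal(idx$arm[idx$patient_id == "p2"], "ter")     # earliest wins
  expect_equal(idx$index_date[idx$patient_id == "p2"], as.Date("2013-06-01"))
  expect_false("p3" %in% idx$patient_id)                   # outside window
})

test_that("same-day tie between two DMTs is an explicit ambiguity error", {
  fills <- data.frame(patient_id = "p9", date = as.Date("2013-05-01"),
                      code = c("DMT_DMF", "DMT_TER"), days_supply = 30L)
  expect_error(assign_index(fills, w, cm), "p9")
})

test_that("PDC counts distinct covered days over the post-index year", {
  mkfills <- function(offsets, supply) data.frame(
    patient_id = "a", date = d0 + offsets, code = "DMT_DMF",
    days_supply = supply, stringsAsFactors = FALSE)
  expect_equal(compute_pdc(mkfills(0, 365), d0, w, "DMT_DMF"), 1.0)
  expect_equal(compute_pdc(mkfills(c(0, 90), 90), d0, w, "DMT_DMF"), 180 / 365)
  # overlapping fills: union of days, not sum of supplies
  expect_equal(compute_pdc(mkfills(c(0, 45), 90), d0, w, "DMT_DMF"), 135 / 365)
  # other drugs' fills never count
  f <- mkfills(0, 365); f$code <- "DMT_TER"
  expect_equal(compute_pdc(f, d0, w, "DMT_DMF"), 0)
  f$days_supply <- 0L
  expect_error(compute_pdc(f, d0, w, "DMT_DMF"), "days_supply")
})

test_that("continuous enrolment allows a single gap up to 30 days", {
  span <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(patient_id = "a",
               start_date = d0 + m[, 1], end_date = d0 + m[, 2])
  }
  expect_true(check_continuous_enrolment(span(-365, 364), d0, w))
  # 25-day interior gap is allowed
  expect_true(check_continuous_enrolment(
    span(-365, -100, -74, 364), d0, w))
  # 45-day gap exceeds the allowance
  expect_false(check_continuous_enrolment(
    span(-365, -100, -54, 364), d0, w))
  # two small gaps fail in single-gap mode but pass in total-days mode
  two_gaps <- span(-365, -200, -189, -100, -89, 364)
  expect_false(check_continuous_enrolment(two_gaps, d0, w))
  w_total <- study_windows(gap_mode = "total")
  expect_true(check_continuous_enrolment(two_gaps, d0, w_total))
  # coverage starting late fails
  expect_false(check_continuous_enrolment(span(-300, 364), d0, w))
})

test_that("outcome definitions date events at the qualifying record", {
  dx <- function(days, code) data.frame(patient_id = "a", date = d0 + days,
                                        code = code, stringsAsFactors = FALSE)
  no_fills <- data.frame(patient_id = character(), date = as.Date(character()),
                         code = character(), days_supply = integer())
  # two T2D diagnoses: event at the second
  ev <- derive_outcome(dx(c(50, 80), "T2D_DX"), no_fills, cm, "t2d")
  expect_equal(ev$event_date, d0 + 80)
  # one diagnosis + one medication fill: event when both are present
  fills <- data.frame(patient_id = "a", date = d0 + 130,
                      code = "DIABETES_RX", days_supply = 30L)
  ev <- derive_outcome(dx(100, "T2D_DX"), fills, cm, "t2d")
  expect_equal(ev$event_date, d0 + 130)
  # a single T2D diagnosis alone is not an event
  expect_equal(nrow(derive_outcome(dx(100, "T2D_DX"), no_fills, cm, "t2d")), 0)
  # single-diagnosis outcomes
  ev <- derive_outcome(dx(200, "CKD_DX"), no_fills, cm, "ckd")
  expect_equal(ev$event_date, d0 + 200)
  # CVD is the earliest of its four components
  ev <- derive_outcome(rbind(dx(150, "MI_DX"), dx(120, "STROKE_DX")),
                       no_fills, cm, "cvd")
  expect_equal(ev$event_date, d0 + 120)
  # composite is the earliest of T2D / CVD / CKD
  ev <- derive_outcome(rbind(dx(c(50, 80), "T2D_DX"), dx(60, "CKD_DX")),
                       no_fills, cm, "composite")
  expect_equal(ev$event_date, d0 + 60)
  expect_error(derive_outcome(dx(1, "T2D_DX"), no_fills, cm, "gout"))
  # records before `from` are ignored
  ev <- derive_outcome(dx(c(-30, 80, 95), "T2D_DX"), no_fills, cm, "t2d",
                       from = c(a = d0))
  expect_equal(ev$event_date, d0 + 95)
})

test_that("follow-up ends at event, >90-day gap, or study end", {
  enr <- data.frame(patient_id = "a", start_date = d0 - 365,
                    end_date = w$study_end)
  # no event: administrative censoring at study end
  fu <- compute_followup(enr, d0, w)
  expect_equal(fu$event, 0L)
  expect_equal(fu$censor_reason, "study_end")
  expect_equal(fu$time_years,
               (as.integer(w$study_end) - as.integer(d0) + 1) / 365.25)
  # 120-day enrolment gap starting day 400: censored at day 400
  enr2 <- data.frame(patient_id = "a",
                     start_date = c(d0 - 365, d0 + 520),
                     end_date = c(d0 + 399, w$study_end))
  fu <- compute_followup(enr2, d0, w)
  expect_equal(fu$censor_reason, "disenrollment")
  expect_equal(fu$time_years, (400 + 1) / 365.25)
  # event before censoring
  fu <- compute_followup(enr, d0, w, event_date = d0 + 350)
  expect_equal(fu$event, 1L)
  expect_equal(fu$censor_reason, "event")
  # on-treatment mode censors at discontinuation before the event
  fu <- compute_followup(enr, d0, w, event_date = d0 + 350,
                         discontinuation = d0 + 300, mode = "on_treatment")
  expect_equal(fu$event, 0L)
  expect_equal(fu$censor_reason, "discontinuation")
  expect_equal(fu$time_years, (300 + 1) / 365.25)
  # itt ignores discontinuation
  fu <- compute_followup(enr, d0, w, event_date = d0 + 350,
                         discontinuation = d0 + 300, mode = "itt")
  expect_equal(fu$event, 1L)
})

test_that("region imputation fills missing values with the mode", {
  coh <- data.frame(region = c("South", "South", "West", NA, NA))
  out <- impute_region(coh)
  expect_equal(out$region[4:5], c("South", "South"))
  # no missing values: unchanged
  expect_identical(impute_region(out), out)
  # tie broken lexicographically, with a message
  coh2 <- data.frame(region = c("West", "South", "West", "South", NA))
  expect_message(out2 <- impute_region(coh2), "South")
  expect_equal(out2$region[5], "South")
  expect_error(impute_region(data.frame(region = c(NA_character_, NA))),
               "all values missing")
  expect_error(impute_region(data.frame(x = 1)), "region")
})

test_that("hand-walked attrition fixture removes (2,1,1,1) in rule order", {
  cfg <- sim_config(n_per_arm = c(dmf = 5, ter = 5),
                    covariates = list(sex = list(type = "binary", p = 0.5)),
                    outcome = list(family = "exponential", rate = 0.05),
                    seed = 77)
  bundle <- simulate_claims(cfg, violations = list(
    low_pdc = 2, enrolment_gap = 1, under_age = 1, prevalent_outcome = 1))
  res <- apply_attrition(bundle, w, cm)
  rep <- res$attrition
  expect_equal(rep$rule,
               c("index_assignment", "pdc_ge_0.6", "continuous_enrolment",
                 "ms_dx_ge_2", "age_ge_18", "no_prevalent_outcome_or_dmt"))
  expect_equal(rep$n_removed, c(0, 2, 1, 0, 1, 1))
  expect_equal(rep$n_after[nrow(rep)], 5)
  expect_equal(nrow(res$cohort), 5)
  # the report telescopes exactly
  expect_equal(rep$n_before[-1], rep$n_after[-nrow(rep)])
  expect_equal(rep$n_after, rep$n_before - rep$n_removed)
})

test_that("violation-free claims round-trip to the intended cohort", {
  cfg <- sim_config(n_per_arm = c(dmf = 15, ter = 15),
                    covariates = list(sex = list(type = "binary", p = 0.5)),
                    outcome = list(family = "exponential", rate = 0.08),
                    seed = 5)
  bundle <- simulate_claims(cfg)
  res <- apply_attrition(bundle, w, cm)
  expect_true(all(res$attrition$n_removed == 0))
  intended <- attr(bundle, "intended")
  expect_setequal(res$cohort$patient_id, intended$patient_id)
  m <- match(res$cohort$patient_id, intended$patient_id)
  expect_equal(res$cohort$arm, as.character(intended$arm[m]))
  expect_true(all(res$cohort$time_years > 0))
})

test_that("prior-DMT and low-MS-diagnosis violations hit their own steps", {
  cfg <- sim_config(n_per_arm = c(dmf = 6, ter = 6),
                    covariates = list(sex = list(type = "binary", p = 0.5)),
                    outcome = list(family = "exponential", rate = 0.05),
                    seed = 13)
  bundle <- simulate_claims(cfg, violations = list(prior_dmt = 2))
  res <- apply_attrition(bundle, w, cm)
  rep <- res$attrition
  expect_equal(rep$n_removed[rep$rule == "no_prevalent_outcome_or_dmt"], 2)
  expect_equal(nrow(res$cohort), 10)
  # a patient with a single pre-index MS diagnosis fails the >= 2 rule
  p <- compliant_patient("solo", d0)
  p$diagnoses <- p$diagnoses[1, ]
  res2 <- apply_attrition(bind_patients(p), w, cm)
  expect_equal(res2$attrition$n_removed[res2$attrition$rule == "ms_dx_ge_2"], 1)
  expect_equal(nrow(res2$cohort), 0)
})

test_that("on-treatment follow-up never exceeds intention-to-treat", {
  cfg <- sim_config(n_per_arm = c(dmf = 40, ter = 40),
                    covariates = list(sex = list(type = "binary", p = 0.5)),
                    outcome = list(family = "exponential", rate = 0.3),
                    seed = 21)
  bundle <- simulate_claims(cfg)
  itt <- apply_attrition(bundle, w, cm, mode = "itt")$cohort
  ot <- apply_attrition(bundle, w, cm, mode = "on_treatment")$cohort
  m <- match(ot$patient_id, itt$patient_id)
  expect_true(all(ot$time_years <= itt$time_years[m] + 1e-12))
  # fills cover only the first post-index year, so late events are censored
  # at discontinuation in on-treatment mode
  expect_true(any(ot$censor_reason == "discontinuation"))
})

test_that("claims bundles validate their tables and export to CSV", {
  p <- compliant_patient("a", d0)
  expect_error(claims_bundle(p$patients,
                             transform(p$enrolment,
                                       end_date = start_date - 1),
                             p$diagnoses, p$fills), "start <= end")
  bad_fills <- transform(p$fills, days_supply = 0L)
  expect_error(claims_bundle(p$patients, p$enrolment, p$diagnoses, bad_fills),
               "days_supply")
  cfg <- sim_config(n_per_arm = c(dmf = 3, ter = 3),
                    covariates = list(sex = list(type = "binary", p = 0.5)),
                    seed = 2)
  dir <- withr::local_tempdir()
  write_claims(simulate_claims(cfg), dir)
  expect_true(all(file.exists(file.path(
    dir, c("patients.csv", "enrolment.csv", "diagnoses.csv", "fills.csv",
           "cohort.csv")))))
  enr <- read.csv(file.path(dir, "enrolment.csv"))
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", enr$start_date)))
})
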