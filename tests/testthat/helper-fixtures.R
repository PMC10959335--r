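# shared fixtures and independent oracles

d0 <- as.Date("2014-01-01")  # a generic index date inside the index period

# brute-force leave-one-out jackknife of a KM functional (the oracle the fast
# prefix-sum implementation is checked against)
brute_jackknife <- function(time, event, functional, t0) {
  n <- length(time)
  th <- function(tt, ee) {
    cv <- km_estimate(tt, ee)
    if (functional == "rmst") suppressWarnings(rmst(cv, t0))
    else suppressWarnings(cumhaz_at(cv, t0))
  }
  full <- th(time, event)
  vapply(seq_len(n),
         function(i) n * full - (n - 1) * th(time[-i], event[-i]),
         numeric(1))
}

# TRUE iff neither the full sample nor any leave-one-out sample has S(t0) = 0
# (keeps comparisons away from the capped degenerate-tail regime)
loo_surv_positive <- function(time, event, t0) {
  surv_at <- function(tt, ee) {
    cv <- km_estimate(tt, ee)
    k <- findInterval(t0, cv$time)
    if (k == 0) 1 else cv$surv[k]
  }
  if (surv_at(time, event) <= 0) return(FALSE)
  all(vapply(seq_along(time),
             function(i) surv_at(time[-i], event[-i]) > 0, logical(1)))
}

# two-arm exponential config with one binary confounder (the recovery design:
# reference hazard 0.10/yr, hazard ratio 0.7, confounder doubling the hazard
# and pushing patients toward the comparator, ~20% censoring)
confounded_config <- function(seed, n_per_arm, log_hr = log(0.7)) {
  sim_config(
    n_per_arm = c(ref = n_per_arm, trt = n_per_arm),
    covariates = list(sex = list(type = "binary", p = 0.5)),
    propensity = list(trt = c(sex = 1.2)),
    outcome = list(family = "exponential", rate = 0.10,
                   coefs = c(sex = log(2)), log_hr = list(trt = log_hr)),
    censoring = list(admin_horizon_years = 20, rate = 0.02),
    seed = seed)
}

# randomized, no-effect two-arm config
null_config <- function(seed, n_per_arm) {
  sim_config(
    n_per_arm = c(ref = n_per_arm, trt = n_per_arm),
    covariates = list(sex = list(type = "binary", p = 0.5)),
    outcome = list(family = "exponential", rate = 0.10),
    censoring = list(admin_horizon_years = 20, rate = 0.02),
    seed = seed)
}

fma_formula <- survival::Surv(time_years, event) ~ arm + sex

# claims fixture for one patient: full compliance around index date `idx`
compliant_patient <- function(id, idx, arm = "dmf", age = 40,
                              windows = study_windows(), cm = code_map()) {
  drug <- cm$dmt[[arm]]
  list(
    patients = data.frame(
      patient_id = id,
      birth_date = as.Date(as.integer(idx) - round(age * 365.25 + 180),
                           origin = "1970-01-01"),
      region = "South", stringsAsFactors = FALSE),
    enrolment = data.frame(patient_id = id, start_date = idx - 365L,
                           end_date = windows$study_end,
                           stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = id, date = idx - c(200L, 100L),
                           code = cm$ms_dx[1], stringsAsFactors = FALSE),
    fills = data.frame(patient_id = id, date = idx + c(0L, 90L, 180L, 270L),
                       code = drug, days_supply = 90L,
                       stringsAsFactors = FALSE))
}

bind_patients <- function(...) {
  ps <- list(...)
  claims_bundle(
    patients = do.call(rbind, lapply(ps, `[[`, "patients")),
    enrolment = do.call(rbind, lapply(ps, `[[`, "enrolment")),
    diagnoses = do.call(rbind, lapply(ps, `[[`, "diagnoses")),
    fills = do.call(rbind, lapply(ps, `[[`, "fills")))
}
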