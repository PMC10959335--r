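#' Study window and rule configuration
#'
#' Calendar windows and rule thresholds for deriving a new-user cohort from
#' claims: the index period, pre/post-index lengths, the continuous-enrolment
#' gap allowance, the disenrollment gap defining loss to follow-up, the PDC
#' adherence threshold, and the supply gap defining treatment discontinuation.
#'
#' Two conventions the literature leaves open are exposed as flags:
#' `pdc_include_index` (does the index day count toward the PDC window; default
#' `TRUE`, the post-index year includes the index day) and
#' `pre_index_include_index` (is the index day part of the pre-index lookback;
#' default `FALSE`, pre-index is `[index-365, index-1]`). `gap_mode` chooses
#' between allowing a single enrolment gap up to the allowance (`"single"`,
#' default) or capping total gap days (`"total"`).
#'
#' @param index_start,index_end bounds of the index period.
#' @param study_start,study_end bounds of the study database period.
#' @param pre_index_days,post_index_days lookback / adherence window lengths.
#' @param enrolment_gap_allowance maximum permitted enrolment gap, days.
#' @param disenrollment_gap enrolment gap (days) that triggers censoring.
#' @param pdc_threshold minimum proportion of days covered, in (0, 1].
#' @param discontinuation_gap supply gap (days) defining discontinuation.
#' @param gap_mode `"single"` or `"total"` (see Details).
#' @param pdc_include_index,pre_index_include_index convention flags.
#' @return list of class `study_windows`.
#' @export
study_windows <- function(index_start = as.Date("2013-01-01"),
                          index_end = as.Date("2018-12-31"),
                          study_start = as.Date("2012-01-01"),
                          study_end = as.Date("2019-12-31"),
                          pre_index_days = 365L, post_index_days = 365L,
                          enrolment_gap_allowance = 30L,
                          disenrollment_gap = 90L,
                          pdc_threshold = 0.60,
                          discontinuation_gap = 60L,
                          gap_mode = c("single", "total"),
                          pdc_include_index = TRUE,
                          pre_index_include_index = FALSE) {
  stopifnot(index_start <= index_end, study_start <= index_start,
            index_end <= study_end)
  if (pdc_threshold <= 0 || pdc_threshold > 1)
    stop("pdc_threshold must be in (0, 1]")
  structure(list(index_start = index_start, index_end = index_end,
                 study_start = study_start, study_end = study_end,
                 pre_index_days = as.integer(pre_index_days),
                 post_index_days = as.integer(post_index_days),
                 enrolment_gap_allowance = as.integer(enrolment_gap_allowance),
                 disenrollment_gap = as.integer(disenrollment_gap),
                 pdc_threshold = pdc_threshold,
                 discontinuation_gap = as.integer(discontinuation_gap),
                 gap_mode = match.arg(gap_mode),
                 pdc_include_index = pdc_include_index,
                 pre_index_include_index = pre_index_include_index),
            class = "study_windows")
}

#' Synthetic code vocabulary
#'
#' Code sets used to recognize diagnoses and drug fills in the synthetic
#' claims vocabulary: multiple-sclerosis diagnoses, the outcome conditions
#' (type 2 diabetes, acute heart failure, atherosclerosis, myocardial
#' infarction, stroke, chronic kidney disease), diabetes medications, and the
#' per-arm disease-modifying-therapy drug codes. Code sets must be non-empty
#' and drug classes disjoint.
#'
#' @param dmt named character vector, one drug code per treatment arm.
#' @return list of class `code_map`.
#' @export
code_map <- function(dmt = c(dmf = "DMT_DMF", fin = "DMT_FIN",
                             gla = "DMT_GLA", ter = "DMT_TER")) {
  cm <- list(ms_dx = "MS_DX",
             t2d = "T2D_DX", diabetes_med = "DIABETES_RX",
             ahf = "AHF_DX", atherosclerosis = "ATH_DX",
             mi = "MI_DX", stroke = "STROKE_DX", ckd = "CKD_DX",
             dmt = dmt)
  if (anyDuplicated(c(cm$diabetes_med, cm$dmt)))
    stop("drug code classes must be disjoint")
  structure(cm, class = "code_map")
}

outcome_dx_codes <- function(cm) {
  c(cm$t2d, cm$ahf, cm$atherosclerosis, cm$mi, cm$stroke, cm$ckd)
}

#' Bundle raw claims tables
#'
#' Validates and packages the four raw tables the cohort builder consumes:
#' patient demographics (`patient_id`, `birth_date`, plus baseline covariate
#' columns), enrolment spans (`patient_id`, `start_date`, `end_date`),
#' diagnosis records (`patient_id`, `date`, `code`) and prescription fills
#' (`patient_id`, `date`, `code`, `days_supply`).
#'
#' @param patients,enrolment,diagnoses,fills data frames as above.
#' @return list of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, enrolment, diagnoses, fills) {
  stopifnot(all(c("patient_id", "birth_date") %in% names(patients)),
            all(c("patient_id", "start_date", "end_date") %in% names(enrolment)),
            all(c("patient_id", "date", "code") %in% names(diagnoses)),
            all(c("patient_id", "date", "code", "days_supply") %in% names(fills)))
  if (any(enrolment$end_date < enrolment$start_date))
    stop("enrolment spans must have start <= end")
  if (nrow(fills) && any(fills$days_supply < 1))
    stop("data error: non-positive days_supply")
  structure(list(patients = patients, enrolment = enrolment,
                 diagnoses = diagnoses, fills = fills),
            class = "claims_bundle")
}

#' Assign index date and arm from DMT fills
#'
#' The index date is each patient's earliest qualifying DMT fill inside the
#' index period; the arm is that fill's drug. Patients with no qualifying fill
#' are omitted. Two different DMTs filled on the same first date is an
#' ambiguity error naming the patients (explicit handling is forced rather
#' than silent arbitrary assignment).
#'
#' @param fills fills table (see [claims_bundle()]).
#' @param windows a [study_windows()].
#' @param cm a [code_map()].
#' @return data.frame `patient_id`, `index_date`, `arm`.
#' @export
assign_index <- function(fills, windows, cm) {
  f <- fills[fills$code %in% cm$dmt &
             fills$date >= windows$index_start &
             fills$date <= windows$index_end, , drop = FALSE]
  if (!nrow(f))
    return(data.frame(patient_id = character(), index_date = as.Date(character()),
                      arm = character(), stringsAsFactors = FALSE))
  f <- f[order(f$patient_id, f$date), ]
  first_date <- tapply(as.integer(f$date), f$patient_id, min)
  f$is_first <- as.integer(f$date) == first_date[f$patient_id]
  ff <- f[f$is_first, ]
  n_drugs <- tapply(ff$code, ff$patient_id, function(x) length(unique(x)))
  amb <- names(n_drugs)[n_drugs > 1]
  if (length(amb))
    stop("ambiguous index: two DMTs filled on the same first date for patient(s) ",
         paste(amb, collapse = ", "))
  ff <- ff[!duplicated(ff$patient_id), ]
  arm_of <- setNames(names(cm$dmt), cm$dmt)
  data.frame(patient_id = ff$patient_id, index_date = ff$date,
             arm = unname(arm_of[ff$code]), stringsAsFactors = FALSE,
             row.names = NULL)
}

# distinct covered days for a set of [start, start+supply-1] intervals
# clipped to [lo, hi]; integer day arithmetic.
covered_days <- function(starts, supplies, lo, hi) {
  if (!length(starts)) return(integer(0))
  s <- pmax(as.integer(starts), lo)
  e <- pmin(as.integer(starts) + as.integer(supplies) - 1L, hi)
  keep <- s <= e
  if (!any(keep)) return(integer(0))
  unique(unlist(mapply(seq, s[keep], e[keep], SIMPLIFY = FALSE)))
}

#' Proportion of days covered for the index drug
#'
#' PDC over the post-index adherence window: the number of distinct days in
#' the window covered by the union of the index drug's supply intervals,
#' divided by the window length. By default the window is
#' `[index, index + post_index_days - 1]` (the index day counts).
#'
#' @param fills this patient's fills table.
#' @param index_date the patient's index date.
#' @param windows a [study_windows()].
#' @param drug_codes character vector of the index drug's codes.
#' @return PDC as a fraction in `[0, 1]`.
#' @export
#' @examples
#' w <- study_windows()
#' f <- data.frame(patient_id = "a",
#'                 date = as.Date("2014-01-01") + c(0, 90),
#'                 code = "DMT_DMF", days_supply = 90)
#' compute_pdc(f, as.Date("2014-01-01"), w, "DMT_DMF")  # 180/365
compute_pdc <- function(fills, index_date, windows, drug_codes) {
  if (nrow(fills) && any(fills$days_supply < 1))
    stop("data error: non-positive days_supply")
  lo <- as.integer(index_date) + if (windows$pdc_include_index) 0L else 1L
  hi <- as.integer(index_date) + windows$post_index_days - 1L
  f <- fills[fills$code %in% drug_codes, , drop = FALSE]
  length(covered_days(f$date, f$days_supply, lo, hi)) /
    (hi - lo + 1L)
}

# merge spans into disjoint sorted [start, end] integer runs
merge_spans <- function(starts, ends) {
  o <- order(starts)
  s <- as.integer(starts)[o]; e <- as.integer(ends)[o]
  ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# uncovered gaps (lengths, in days) of merged spans within [lo, hi]
enrolment_gaps <- function(enrol, lo, hi) {
  if (!nrow(enrol)) return(hi - lo + 1L)
  m <- merge_spans(enrol$start_date, enrol$end_date)
  m <- m[m[, "end"] >= lo & m[, "start"] <= hi, , drop = FALSE]
  if (!nrow(m)) return(hi - lo + 1L)
  m[, "start"] <- pmax(m[, "start"], lo)
  m[, "end"] <- pmin(m[, "end"], hi)
  gaps <- integer(0)
  if (m[1, "start"] > lo) gaps <- c(gaps, m[1, "start"] - lo)
  if (nrow(m) > 1)
    gaps <- c(gaps, m[-1, "start"] - m[-nrow(m), "end"] - 1L)
  if (m[nrow(m), "end"] < hi) gaps <- c(gaps, hi - m[nrow(m), "end"])
  gaps[gaps > 0]
}

#' Continuous-enrolment check around the index date
#'
#' Tests whether the window from `pre_index_days` before index through
#' `post_index_days - 1` after index is covered by the patient's enrolment
#' spans, up to the configured gap allowance: in `"single"` mode at most one
#' gap of at most `enrolment_gap_allowance` days is permitted; in `"total"`
#' mode gaps may not sum to more than the allowance.
#'
#' @param enrolment this patient's enrolment spans.
#' @param index_date the patient's index date.
#' @param windows a [study_windows()].
#' @return logical.
#' @export
check_continuous_enrolment <- function(enrolment, index_date, windows) {
  lo <- as.integer(index_date) - windows$pre_index_days
  hi <- as.integer(index_date) + windows$post_index_days - 1L
  gaps <- enrolment_gaps(enrolment, lo, hi)
  if (!length(gaps)) return(TRUE)
  if (windows$gap_mode == "single")
    length(gaps) == 1L && gaps <= windows$enrolment_gap_allowance
  else
    sum(gaps) <= windows$enrolment_gap_allowance
}

#' First qualifying event date for an outcome definition
#'
#' Event definitions: type 2 diabetes requires two T2D diagnoses, or one T2D
#' diagnosis plus one diabetes-medication fill (the event is dated at the
#' second qualifying record, when the definition is first satisfied); acute
#' heart failure, atherosclerosis, myocardial infarction, stroke and chronic
#' kidney disease each require a single diagnosis; `cvd` is the earliest of
#' its four components; `composite` the earliest of T2D, CVD and CKD.
#'
#' @param diagnoses,fills record tables (any number of patients).
#' @param cm a [code_map()].
#' @param outcome one of `"t2d"`, `"ahf"`, `"atherosclerosis"`, `"mi"`,
#'   `"stroke"`, `"cvd"`, `"ckd"`, `"composite"`.
#' @param from optional named vector of dates (by patient id): records
#'   strictly before a patient's `from` date are ignored (used to restrict to
#'   post-index records).
#' @return data.frame `patient_id`, `event_date` (patients with no event
#'   omitted).
#' @export
derive_outcome <- function(diagnoses, fills, cm, outcome, from = NULL) {
  outcome <- match.arg(outcome, c("t2d", "ahf", "atherosclerosis", "mi",
                                  "stroke", "cvd", "ckd", "composite"))
  clip <- function(tab) {
    if (is.null(from) || !nrow(tab)) return(tab)
    lim <- from[tab$patient_id]
    tab[!is.na(lim) & as.integer(tab$date) >= as.integer(lim), , drop = FALSE]
  }
  dx <- clip(diagnoses); fl <- clip(fills)

  single_dx <- function(codes) {
    d <- dx[dx$code %in% codes, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    agg <- tapply(as.integer(d$date), d$patient_id, min)
    data.frame(patient_id = names(agg),
               event_date = as.Date(as.vector(agg), origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }
  t2d_events <- function() {
    d <- dx[dx$code %in% cm$t2d, , drop = FALSE]
    f <- fl[fl$code %in% cm$diabetes_med, , drop = FALSE]
    ids <- union(d$patient_id, f$patient_id)
    if (!length(ids)) return(NULL)
    res <- vapply(ids, function(id) {
      dd <- sort(as.integer(d$date[d$patient_id == id]))
      fd <- sort(as.integer(f$date[f$patient_id == id]))
      cand <- c(if (length(dd) >= 2) dd[2],
                if (length(dd) >= 1 && length(fd) >= 1) max(dd[1], fd[1]))
      if (length(cand)) min(cand) else NA_integer_
    }, numeric(1))
    res <- res[!is.na(res)]
    if (!length(res)) return(NULL)
    data.frame(patient_id = names(res),
               event_date = as.Date(as.vector(res), origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }
  earliest_of <- function(parts) {
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(data.frame(patient_id = character(),
                                          event_date = as.Date(character())))
    all <- do.call(rbind, parts)
    agg <- tapply(as.integer(all$event_date), all$patient_id, min)
    data.frame(patient_id = names(agg),
               event_date = as.Date(as.vector(agg), origin = "1970-01-01"),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  cvd_parts <- function() list(single_dx(cm$ahf), single_dx(cm$atherosclerosis),
                               single_dx(cm$mi), single_dx(cm$stroke))
  out <- switch(outcome,
    t2d = earliest_of(list(t2d_events())),
    ahf = earliest_of(list(single_dx(cm$ahf))),
    atherosclerosis = earliest_of(list(single_dx(cm$atherosclerosis))),
    mi = earliest_of(list(single_dx(cm$mi))),
    stroke = earliest_of(list(single_dx(cm$stroke))),
    ckd = earliest_of(list(single_dx(cm$ckd))),
    cvd = earliest_of(cvd_parts()),
    composite = earliest_of(c(list(t2d_events(), single_dx(cm$ckd)), cvd_parts()))
  )
  out
}

# discontinuation of the index drug: first supply gap > discontinuation_gap
# days after exhaustion; returns the day after the last covered day, or NA if
# supply runs to within the gap of study_end.
discontinuation_date <- function(fills, index_date, windows, drug_codes) {
  f <- fills[fills$code %in% drug_codes &
             as.integer(fills$date) >= as.integer(index_date), , drop = FALSE]
  if (!nrow(f)) return(index_date)          # never covered: discontinued at index
  runs <- merge_spans(f$date, as.integer(f$date) + f$days_supply - 1L)
  nxt <- c(runs[-1, "start"], as.integer(windows$study_end) + 1L)
  gap <- nxt - runs[, "end"] - 1L
  hit <- which(gap > windows$discontinuation_gap)
  if (!length(hit)) return(as.Date(NA))
  as.Date(runs[hit[1], "end"] + 1L, origin = "1970-01-01")
}

#' Follow-up time, event indicator and censoring reason for one patient
#'
#' Follow-up runs from index to the earliest of: the first event, the start of
#' the first enrolment gap longer than `disenrollment_gap` days after index,
#' the end of the study period, and -- in `"on_treatment"` mode -- the
#' treatment discontinuation date. An event on the index day is counted at the
#' end of that day (follow-up of one day), keeping follow-up strictly
#' positive.
#'
#' @param enrolment this patient's enrolment spans.
#' @param index_date the patient's index date.
#' @param windows a [study_windows()].
#' @param event_date first qualifying event date, or `NA`.
#' @param discontinuation discontinuation date, or `NA` (only used in
#'   `"on_treatment"` mode).
#' @param mode `"itt"` (intention-to-treat) or `"on_treatment"`.
#' @return list `time_years`, `event` (0/1), `censor_reason`.
#' @export
compute_followup <- function(enrolment, index_date, windows,
                             event_date = as.Date(NA),
                             discontinuation = as.Date(NA),
                             mode = c("itt", "on_treatment")) {
  mode <- match.arg(mode)
  idx <- as.integer(index_date)
  ends <- c(study_end = as.integer(windows$study_end))
  gaps_end <- disenrollment_day(enrolment, idx, windows)
  if (!is.na(gaps_end)) ends <- c(ends, disenrollment = gaps_end)
  if (mode == "on_treatment" && !is.na(discontinuation))
    ends <- c(ends, discontinuation = as.integer(discontinuation))
  cens_day <- min(ends)
  cens_reason <- names(ends)[which.min(ends)]
  ev <- !is.na(event_date) && as.integer(event_date) <= cens_day
  end_day <- if (ev) as.integer(event_date) else cens_day
  list(time_years = max(end_day - idx, 0L) / 365.25 + 1 / 365.25,
       event = as.integer(ev),
       censor_reason = if (ev) "event" else cens_reason)
}

# first day of an enrolment gap > disenrollment_gap after index (NA if none);
# enrolment ending before study_end counts as a terminal gap.
disenrollment_day <- function(enrolment, idx, windows) {
  hi <- as.integer(windows$study_end)
  m <- merge_spans(enrolment$start_date, enrolment$end_date)
  m <- m[m[, "end"] >= idx, , drop = FALSE]
  if (!nrow(m) || m[1, "start"] > idx) return(idx)
  nxt <- c(m[-1, "start"], hi + 1L)
  gap <- nxt - m[, "end"] - 1L
  hit <- which(gap > windows$disenrollment_gap)
  if (!length(hit)) return(NA_integer_)
  unname(m[hit[1], "end"]) + 1L
}

#' Apply the full attrition cascade and build the analysis cohort
#'
#' Applies, in order: index assignment; PDC at least the threshold;
#' continuous enrolment (gap allowance); at least two multiple-sclerosis
#' diagnoses pre-index; age at least 18 at index; exclusion of patients with
#' any outcome diagnosis or any study-DMT fill during the pre-index period.
#' Each step is recorded in an attrition report that telescopes exactly to the
#' final cohort size. The retained patients are then given an outcome event
#' date ([derive_outcome()]) and follow-up ([compute_followup()]).
#'
#' @param bundle a [claims_bundle()].
#' @param windows a [study_windows()].
#' @param cm a [code_map()].
#' @param outcome outcome name passed to [derive_outcome()].
#' @param mode follow-up mode, `"itt"` or `"on_treatment"`.
#' @return list with `cohort` (analysis table: one row per retained patient)
#'   and `attrition` (data.frame `rule`, `n_before`, `n_removed`, `n_after`,
#'   with a per-arm count matrix in `attr(, "per_arm")`).
#' @export
apply_attrition <- function(bundle, windows, cm, outcome = "composite",
                            mode = c("itt", "on_treatment")) {
  mode <- match.arg(mode)
  if (!inherits(bundle, "claims_bundle")) stop("missing required claims tables")
  idx <- assign_index(bundle$fills, windows, cm)
  all_ids <- unique(bundle$patients$patient_id)

  steps <- list()
  record <- function(rule, before_ids, after_ids) {
    steps[[length(steps) + 1L]] <<- list(rule = rule,
                                         n_before = length(before_ids),
                                         n_removed = length(before_ids) - length(after_ids),
                                         n_after = length(after_ids))
  }
  record("index_assignment", all_ids, idx$patient_id)
  ids <- idx$patient_id
  index_of <- setNames(idx$index_date, idx$patient_id)
  arm_of <- setNames(idx$arm, idx$patient_id)

  by_pat <- function(tab) split(tab, tab$patient_id)
  fills_by <- by_pat(bundle$fills)
  enrol_by <- by_pat(bundle$enrolment)
  dx_by <- by_pat(bundle$diagnoses)
  empty_fills <- bundle$fills[0, ]; empty_enrol <- bundle$enrolment[0, ]
  empty_dx <- bundle$diagnoses[0, ]
  gf <- function(id) if (!is.null(fills_by[[id]])) fills_by[[id]] else empty_fills
  ge <- function(id) if (!is.null(enrol_by[[id]])) enrol_by[[id]] else empty_enrol
  gd <- function(id) if (!is.null(dx_by[[id]])) dx_by[[id]] else empty_dx
  pre_lo <- function(id) as.integer(index_of[[id]]) - windows$pre_index_days
  pre_hi <- function(id) as.integer(index_of[[id]]) -
    if (windows$pre_index_include_index) 0L else 1L

  # PDC >= threshold
  keep <- vapply(ids, function(id)
    compute_pdc(gf(id), index_of[[id]], windows,
                cm$dmt[[arm_of[[id]]]]) >= windows$pdc_threshold, logical(1))
  record(sprintf("pdc_ge_%g", windows$pdc_threshold), ids, ids[keep]); ids <- ids[keep]

  # continuous enrolment
  keep <- vapply(ids, function(id)
    check_continuous_enrolment(ge(id), index_of[[id]], windows), logical(1))
  record("continuous_enrolment", ids, ids[keep]); ids <- ids[keep]

  # >= 2 MS diagnoses pre-index
  keep <- vapply(ids, function(id) {
    d <- gd(id)
    sum(d$code %in% cm$ms_dx &
        as.integer(d$date) >= pre_lo(id) &
        as.integer(d$date) <= pre_hi(id)) >= 2L
  }, logical(1))
  record("ms_dx_ge_2", ids, ids[keep]); ids <- ids[keep]

  # age >= 18 at index
  birth_of <- setNames(bundle$patients$birth_date, bundle$patients$patient_id)
  keep <- vapply(ids, function(id)
    floor((as.integer(index_of[[id]]) - as.integer(birth_of[[id]])) / 365.25) >= 18,
    logical(1))
  record("age_ge_18", ids, ids[keep]); ids <- ids[keep]

  # no prevalent outcome diagnosis, no pre-index DMT fill
  out_codes <- outcome_dx_codes(cm)
  keep <- vapply(ids, function(id) {
    d <- gd(id); f <- gf(id)
    prev_dx <- any(d$code %in% out_codes &
                   as.integer(d$date) >= pre_lo(id) &
                   as.integer(d$date) <= pre_hi(id))
    prev_rx <- any(f$code %in% cm$dmt &
                   as.integer(f$date) >= pre_lo(id) &
                   as.integer(f$date) <= pre_hi(id))
    !prev_dx && !prev_rx
  }, logical(1))
  record("no_prevalent_outcome_or_dmt", ids, ids[keep]); ids <- ids[keep]

  report <- do.call(rbind, lapply(steps, as.data.frame))
  stopifnot(all(report$n_after == report$n_before - report$n_removed))

  # outcome + follow-up for retained patients
  ev <- derive_outcome(bundle$diagnoses, bundle$fills, cm, outcome,
                       from = index_of[ids])
  ev_of <- setNames(ev$event_date, ev$patient_id)
  rows <- lapply(ids, function(id) {
    disc <- if (mode == "on_treatment")
      discontinuation_date(gf(id), index_of[[id]], windows,
                           cm$dmt[[arm_of[[id]]]])
    else as.Date(NA)
    e_date <- if (id %in% names(ev_of)) ev_of[[id]] else as.Date(NA)
    fu <- compute_followup(ge(id), index_of[[id]], windows, e_date, disc, mode)
    data.frame(patient_id = id, arm = arm_of[[id]],
               index_date = index_of[[id]],
               time_years = fu$time_years, event = fu$event,
               censor_reason = fu$censor_reason, stringsAsFactors = FALSE)
  })
  cohort <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), arm = character(),
               index_date = as.Date(character()), time_years = numeric(),
               event = integer(), censor_reason = character())
  demo <- bundle$patients[match(cohort$patient_id, bundle$patients$patient_id),
                          setdiff(names(bundle$patients),
                                  c("patient_id", "birth_date")), drop = FALSE]
  if (nrow(cohort)) {
    cohort$age <- floor((as.integer(cohort$index_date) -
                         as.integer(birth_of[cohort$patient_id])) / 365.25)
    cohort <- cbind(cohort, demo)
  }
  row.names(cohort) <- NULL
  attr(report, "per_arm") <- table(arm_of[ids])
  list(cohort = cohort, attrition = report)
}

#' Impute missing region to the modal category
#'
#' Missing values in the `region` column are set to the most frequent
#' non-missing category (mode imputation). A tie between modes is broken
#' lexicographically and reported via a message.
#'
#' @param cohort a cohort data.frame with a `region` column.
#' @return the cohort with `region` completed.
#' @export
impute_region <- function(cohort) {
  r <- cohort$region
  if (is.null(r)) stop("no region column present")
  miss <- is.na(r) | (!is.factor(r) & r == "")
  if (all(miss)) stop("cannot impute region: all values missing")
  if (!any(miss)) return(cohort)
  tab <- table(as.character(r[!miss]))
  modes <- names(tab)[tab == max(tab)]
  mode <- sort(modes)[1]
  if (length(modes) > 1)
    message("region mode tie (", paste(sort(modes), collapse = ", "),
            "); using '", mode, "'")
  if (is.factor(r)) {
    levels(r) <- union(levels(r), mode)
    r[miss] <- mode
  } else r[miss] <- mode
  cohort$region <- r
  cohort
}
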