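#' Generate raw synthetic claims tables for a configured cohort
#'
#' Emits patient demographics, enrolment spans, diagnosis records and
#' prescription fills such that applying the cohort builder
#' ([apply_attrition()]) recovers the cohort intended by the configuration:
#' every compliant patient gets an index DMT fill sequence covering the
#' post-index year (PDC about 0.99), continuous enrolment from one year before
#' index to the study end, two pre-index multiple-sclerosis diagnoses, and --
#' if their simulated outcome occurred -- a pair of type 2 diabetes diagnoses
#' dating the event at the second record.
#'
#' Rule violations can be injected for attrition testing via exact patient
#' counts (chosen at random under the config seed, disjoint across rules):
#' \describe{
#'   \item{`low_pdc`}{only a single 90-day fill (PDC about 0.25)}
#'   \item{`enrolment_gap`}{a 44-day enrolment gap in the pre-index year}
#'   \item{`under_age`}{age 17 at index}
#'   \item{`prevalent_outcome`}{a T2D diagnosis 50 days before index}
#'   \item{`prior_dmt`}{a fill of another study DMT during pre-index (dated
#'     before the index period so index assignment is unaffected)}
#' }
#'
#' @param config a [sim_config()]; arm labels must match `names(cm$dmt)`.
#' @param violations named list/vector of per-rule violator counts (see
#'   Details); all default to 0.
#' @param windows a [study_windows()].
#' @param cm a [code_map()].
#' @return a [claims_bundle()] with attribute `"intended"`: the
#'   [simulate_cohort()] table the bundle was built from.
#' @export
simulate_claims <- function(config, violations = list(),
                            windows = study_windows(),
                            cm = code_map()) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(config$arm_labels %in% names(cm$dmt)))
    stop("config error in 'arm_labels': no DMT code for ",
         paste(setdiff(config$arm_labels, names(cm$dmt)), collapse = ", "))
  viol <- list(low_pdc = 0L, enrolment_gap = 0L, under_age = 0L,
               prevalent_outcome = 0L, prior_dmt = 0L)
  for (nm in names(violations)) {
    if (!nm %in% names(viol)) stop("unknown violation rule: ", nm)
    viol[[nm]] <- as.integer(violations[[nm]])
  }

  cohort <- simulate_cohort(config)
  n <- nrow(cohort)
  if (sum(unlist(viol)) > n) stop("more violators requested than patients")
  set.seed(config$seed + 1L)

  # assign violators: disjoint random sets, one rule each
  shuffled <- sample(cohort$patient_id)
  vsets <- list(); pos <- 1L
  for (nm in names(viol)) {
    k <- viol[[nm]]
    vsets[[nm]] <- if (k > 0) shuffled[pos:(pos + k - 1L)] else character(0)
    pos <- pos + k
  }

  # index dates: uniform over the index period, but kept >= 60 days after the
  # period start for prior-DMT violators so their pre-index fill can predate
  # the index period
  span <- as.integer(windows$index_end) - as.integer(windows$index_start)
  off <- sample.int(span + 1L, n, replace = TRUE) - 1L
  prior_ids <- cohort$patient_id %in% vsets$prior_dmt
  off[prior_ids] <- 60L + sample.int(240L, sum(prior_ids), replace = TRUE)
  index <- as.Date(as.integer(windows$index_start) + off,
                   origin = "1970-01-01")
  names(index) <- cohort$patient_id

  age <- if (!is.null(cohort$age)) cohort$age else rep(45, n)
  age[cohort$patient_id %in% vsets$under_age] <- 17
  birth <- as.Date(as.integer(index) - round(age * 365.25 + 180),
                   origin = "1970-01-01")

  patients <- cbind(
    data.frame(patient_id = cohort$patient_id, birth_date = birth,
               stringsAsFactors = FALSE),
    cohort[, setdiff(names(cohort),
                     c("patient_id", "arm", "age", "time_years", "event",
                       "censor_reason")), drop = FALSE])

  # enrolment: [index - 365, study_end], with a 44-day pre-index gap injected
  # for enrolment_gap violators
  lo <- as.integer(index) - 365L
  hi <- as.integer(windows$study_end)
  gap_ids <- cohort$patient_id %in% vsets$enrolment_gap
  enr <- data.frame(patient_id = cohort$patient_id,
                    start_date = as.Date(lo, origin = "1970-01-01"),
                    end_date = as.Date(hi, origin = "1970-01-01"),
                    stringsAsFactors = FALSE)
  if (any(gap_ids)) {
    g1 <- data.frame(patient_id = cohort$patient_id[gap_ids],
                     start_date = as.Date(lo[gap_ids], origin = "1970-01-01"),
                     end_date = as.Date(as.integer(index[gap_ids]) - 200L,
                                        origin = "1970-01-01"))
    g2 <- data.frame(patient_id = cohort$patient_id[gap_ids],
                     start_date = as.Date(as.integer(index[gap_ids]) - 155L,
                                          origin = "1970-01-01"),
                     end_date = as.Date(hi, origin = "1970-01-01"))
    enr <- rbind(enr[!gap_ids, ], g1, g2)
  }

  drug <- unname(cm$dmt[as.character(cohort$arm)])
  low_ids <- cohort$patient_id %in% vsets$low_pdc
  fill_offsets <- c(0L, 90L, 180L, 270L)
  fills <- do.call(rbind, lapply(which(!low_ids), function(i)
    data.frame(patient_id = cohort$patient_id[i],
               date = as.Date(as.integer(index[i]) + fill_offsets,
                              origin = "1970-01-01"),
               code = drug[i], days_supply = 90L, stringsAsFactors = FALSE)))
  if (any(low_ids))
    fills <- rbind(fills,
      data.frame(patient_id = cohort$patient_id[low_ids],
                 date = index[low_ids], code = drug[low_ids],
                 days_supply = 90L, stringsAsFactors = FALSE))
  # prior-DMT violators: a different study DMT filled 30 days before the
  # index period opens -- inside their pre-index year (their index is at most
  # 300 days into the period) but outside the index window, so index
  # assignment is unaffected
  if (any(prior_ids)) {
    other <- vapply(as.character(cohort$arm[prior_ids]), function(a)
      cm$dmt[[setdiff(names(cm$dmt), a)[1]]], character(1))
    fills <- rbind(fills,
      data.frame(patient_id = cohort$patient_id[prior_ids],
                 date = windows$index_start - 30L,
                 code = unname(other), days_supply = 30L,
                 stringsAsFactors = FALSE))
  }

  # diagnoses: two MS codes pre-index for everyone; outcome (T2D) pair at the
  # simulated event time; prevalent T2D 50 days pre-index for violators
  ms <- data.frame(patient_id = rep(cohort$patient_id, 2),
                   date = as.Date(c(as.integer(index) - 200L,
                                    as.integer(index) - 100L),
                                  origin = "1970-01-01"),
                   code = cm$ms_dx[1], stringsAsFactors = FALSE)
  evd <- pmax(1L, round(cohort$time_years * 365.25))
  has_event <- cohort$event == 1L
  ev1 <- as.integer(index) + pmax(evd - 7L, 0L)
  ev2 <- as.integer(index) + evd
  diagnoses <- ms
  if (any(has_event))
    diagnoses <- rbind(diagnoses, data.frame(
      patient_id = rep(cohort$patient_id[has_event], 2),
      date = as.Date(c(ev1[has_event], ev2[has_event]), origin = "1970-01-01"),
      code = cm$t2d[1], stringsAsFactors = FALSE))
  prev_ids <- cohort$patient_id %in% vsets$prevalent_outcome
  if (any(prev_ids))
    diagnoses <- rbind(diagnoses, data.frame(
      patient_id = cohort$patient_id[prev_ids],
      date = as.Date(as.integer(index[prev_ids]) - 50L, origin = "1970-01-01"),
      code = cm$t2d[1], stringsAsFactors = FALSE))

  bundle <- claims_bundle(patients, enr, diagnoses, fills)
  attr(bundle, "intended") <- cohort
  attr(bundle, "violators") <- vsets
  bundle
}

#' Write a claims bundle and cohort to CSV files
#'
#' Writes `patients.csv`, `enrolment.csv`, `diagnoses.csv`, `fills.csv` (and
#' `cohort.csv` for the intended cohort, if present) with ISO-8601 dates.
#'
#' @param bundle a [claims_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "enrolment", "diagnoses", "fills"))
    write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  intended <- attr(bundle, "intended")
  if (!is.null(intended)) {
    x <- intended; attr(x, "audit") <- NULL
    write.csv(x, file.path(dir, "cohort.csv"), row.names = FALSE)
  }
  invisible(dir)
}
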