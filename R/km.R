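#' Kaplan-Meier estimate of a survival sample
#'
#' Product-limit estimator via [survival::survfit()]. Subjects censored at an
#' event time are counted in the risk set for that time (the standard
#' convention: events precede censorings at tied times).
#'
#' @param time nonnegative follow-up durations (years).
#' @param event 0/1 event indicators.
#' @return an object of class `km_curve`: event times (`time`), survival
#'   (`surv`), risk-set sizes and event counts at each event time, the sample
#'   size `n` and the largest observed time `max_time`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))$surv  # 0.75 0.50 0.25 0.00
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty survival sample")
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 n = length(time), max_time = max(time)),
            class = "km_curve")
}

#' @method print km_curve
#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "with", sum(x$n_event),
      "events at", length(x$time), "distinct times\n")
  if (length(x$time))
    print(data.frame(time = x$time, surv = round(x$surv, 4),
                     n_risk = x$n_risk, n_event = x$n_event),
          row.names = FALSE)
  invisible(x)
}

#' @method as.data.frame km_curve
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$surv, at_risk = x$n_risk)
}

# survival at t (step function, right-continuous)
km_surv_at <- function(curve, t) {
  k <- findInterval(t, curve$time)
  if (k == 0) 1 else curve$surv[k]
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Exact step-function integration of the estimated survival curve over
#' `[0, t0]`. If `t0` exceeds the largest observed time the last survival
#' value is carried forward with a warning.
#'
#' @param curve a [km_estimate()] result.
#' @param t0 cut-off time (years), > 0.
#' @return RMST in years, in `[0, t0]`.
#' @export
rmst <- function(curve, t0) {
  stopifnot(inherits(curve, "km_curve"), t0 > 0)
  if (t0 > curve$max_time)
    warning("t0 beyond the last observed time; survival carried forward")
  tt <- curve$time[curve$time <= t0]
  ss <- curve$surv[curve$time <= t0]
  sum(diff(c(0, tt, t0)) * c(1, ss))
}

#' Restricted cumulative hazard -log S(t0)
#'
#' Evaluates the negative log of the Kaplan-Meier survival estimate at the
#' cut-off. A degenerate tail with `S(t0) = 0` is capped at
#' `-log(1 / (2 * r))`, where `r` is the risk-set size at the last event,
#' with a warning (keeps downstream pseudo-values finite).
#'
#' @inheritParams rmst
#' @return nonnegative value.
#' @export
cumhaz_at <- function(curve, t0) {
  stopifnot(inherits(curve, "km_curve"), t0 > 0)
  s <- km_surv_at(curve, t0)
  if (s <= 0) {
    eps <- 1 / (2 * curve$n_risk[length(curve$n_risk)])
    warning("S(t0) = 0; cumulative hazard capped at -log(", signif(eps, 3), ")")
    return(-log(eps))
  }
  -log(s)
}

#' Contrast two arms' functional means into an estimand
#'
#' Maps per-arm means on the pseudo-observation (or probability) scale to the
#' estimand: RMST difference (comparator minus reference, years), restricted
#' hazard ratio (ratio of mean cumulative hazards), or odds ratio for binary
#' outcomes.
#'
#' @param mean0,mean1 reference / comparator arm means.
#' @param functional `"rmst"`, `"cumhaz"`, or `"binary"`.
#' @return the estimand value.
#' @export
#' @examples
#' estimand_from_means(0.10 * 3.2, 0.07 * 3.2, "cumhaz")  # rHR 0.7
estimand_from_means <- function(mean0, mean1, functional) {
  functional <- match.arg(functional, c("rmst", "cumhaz", "binary"))
  switch(functional,
    rmst = mean1 - mean0,
    cumhaz = {
      if (mean0 <= 0) stop("reference-arm mean cumulative hazard <= 0; ratio undefined")
      mean1 / mean0
    },
    binary = {
      if (mean0 <= 0 || mean0 >= 1 || mean1 <= 0 || mean1 >= 1)
        stop("proportions must be strictly inside (0, 1) for an odds ratio")
      (mean1 / (1 - mean1)) / (mean0 / (1 - mean0))
    })
}

# null value of each estimand, used for degenerate strategies and reporting
estimand_null <- function(functional)
  switch(functional, rmst = 0, cumhaz = 1, binary = 1)

# is the estimand a ratio (log-scale averaging)?
estimand_is_ratio <- function(functional) functional %in% c("cumhaz", "binary")
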