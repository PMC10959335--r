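#' Pseudo-observations for restricted survival functionals
#'
#' Builds one pseudo-observation per subject for the restricted mean survival
#' time (`"rmst"`) or the restricted cumulative hazard `-log S(t0)`
#' (`"cumhaz"`), so that censored time-to-event outcomes can be treated as
#' complete-data responses in regression and prediction scoring.
#'
#' `method = "jackknife"` is the classic construction
#' `pseudo_i = n * theta_hat - (n - 1) * theta_hat^(-i)` on the Kaplan-Meier
#' functional, computed by an exact O(n log n) leave-one-out algorithm
#' (prefix sums over the event-time grid; identical to refitting the curve n
#' times). By default the functional jackknifed for `"cumhaz"` is
#' `-log S(t0)` itself; `transform_after = TRUE` instead jackknifes `S(t0)`
#' and applies `-log` to the pseudo-values of survival (an alternative
#' reading of "replace the area by `-log S(t0)`").
#'
#' `method = "covariate_adjusted"` computes inverse-probability-of-censoring
#' weighted (IPCW) pseudo-values: a proportional-hazards model for the
#' censoring distribution given baseline covariates replaces the marginal
#' censoring distribution, making pseudo-values valid under
#' covariate-dependent censoring. The censoring model is fit once and held
#' fixed across leave-one-out (the usual first-order construction); if it
#' cannot be fit the function falls back to the plain jackknife with a
#' warning.
#'
#' @param time,event the survival sample (years; 0/1).
#' @param functional `"rmst"` or `"cumhaz"`.
#' @param t0 cut-off in years.
#' @param method `"jackknife"` or `"covariate_adjusted"`.
#' @param covariates data.frame of baseline covariates (required for the
#'   covariate-adjusted method).
#' @param transform_after jackknife `S(t0)` then apply `-log` (cumhaz only).
#' @return numeric vector of pseudo-observations, with attributes
#'   `functional`, `t0`, `method`.
#' @export
#' @examples
#' # no censoring: pseudo-RMST equals min(T, t0) exactly
#' pseudo_observations(c(1, 2, 3), c(1, 1, 1), "rmst", t0 = 2)  # 1 2 2
pseudo_observations <- function(time, event,
                                functional = c("rmst", "cumhaz"),
                                t0, method = c("jackknife", "covariate_adjusted"),
                                covariates = NULL, transform_after = FALSE) {
  functional <- match.arg(functional)
  method <- match.arg(method)
  n <- length(time)
  if (n < 2) stop("need at least 2 subjects for pseudo-observations")
  stopifnot(length(event) == n, t0 > 0, all(event %in% c(0, 1)))
  if (sum(event) == 0) stop("need at least one event")

  vals <- if (method == "covariate_adjusted") {
    if (is.null(covariates)) stop("covariate_adjusted method requires covariates")
    ipcw_pseudo(time, event, functional, t0, covariates)
  } else {
    jackknife_pseudo(time, event, functional, t0, transform_after)
  }
  structure(vals, functional = functional, t0 = t0,
            method = attr(vals, "method") %||% method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exact leave-one-out Kaplan-Meier jackknife via prefix sums ------------
#
# Leaving out subject i shrinks every risk set at event times <= T_i by one
# and removes the subject's own event; both effects are a rank-1 perturbation
# of the product-limit factors, so all n leave-one-out functionals follow
# from three prefix-sum arrays over the event-time grid.
jackknife_pseudo <- function(time, event, functional, t0, transform_after) {
  curve <- km_estimate(time, event)
  te <- curve$time; d <- curve$n_event; r <- curve$n_risk
  n <- curve$n
  K0 <- sum(te <= t0)

  # log product-limit factors: full-sample (L), risk-set-shrunk (M)
  L <- log1p(-d / r)
  M <- rep(0, length(r))                     # shrunk risk set n_k - 1
  sel <- r > 1
  M[sel] <- log1p(-pmin(d[sel] / (r[sel] - 1), 1))
  Lpre <- c(0, cumsum(L)); Mpre <- c(0, cumsum(M))

  m_i <- findInterval(time, te)              # event times <= T_i
  a_i <- pmin(m_i, K0)
  k_i <- ifelse(event == 1, m_i, 0L)         # own event index (event subjects)
  own <- event == 1 & k_i >= 1 & k_i <= K0
  o_i <- rep(0, n)                           # replacement log-factor at own time
  if (any(own)) {
    ki <- k_i[own]
    o_i[own] <- ifelse(r[ki] > 1, log1p(-(d[ki] - 1) / (r[ki] - 1)), 0)
  }

  # theta for full sample
  theta <- switch(functional,
    rmst = rmst(curve, t0),
    cumhaz = cumhaz_at(curve, t0))

  # log S^{-i}(t0)
  corr <- ifelse(own, o_i - M[pmax(k_i, 1L)], 0)
  logS_i <- Mpre[a_i + 1L] + (Lpre[K0 + 1L] - Lpre[a_i + 1L]) + corr
  bad <- own & !is.finite(M[pmax(k_i, 1L)])  # own factor hit log(0): recompose
  if (any(bad))
    logS_i[bad] <- Mpre[k_i[bad]] + o_i[bad] +
      (Lpre[K0 + 1L] - Lpre[a_i[bad] + 1L])

  if (functional == "cumhaz" && !transform_after) {
    eps <- 1 / (2 * r[length(r)])
    capped <- !is.finite(logS_i)             # leave-one-out S(t0) exactly 0
    if (any(capped)) {
      warning("leave-one-out S(t0) = 0 for ", sum(capped),
              " subject(s); capped")
      logS_i[capped] <- log(eps)
    }
    theta_i <- -logS_i
    return(n * theta - (n - 1) * theta_i)
  }
  if (functional == "cumhaz" && transform_after) {
    # jackknife S(t0), then -log of (clipped) pseudo-survival
    S_full <- km_surv_at(curve, t0)
    ps <- n * S_full - (n - 1) * exp(logS_i)
    eps <- 1 / (2 * n)
    res <- -log(pmin(pmax(ps, eps), 1))
    attr(res, "method") <- "jackknife_surv_then_log"
    return(res)
  }

  # RMST: segment integral with prefix sums of exp(Mpre)*dt and exp(Lpre)*dt
  dt <- if (K0 > 0) c(diff(te[seq_len(K0)]), t0 - te[K0]) else numeric(0)
  lead <- if (K0 > 0) te[1] else t0          # segment [0, te_1)
  PreM <- c(0, cumsum(exp(Mpre[1 + seq_len(K0)]) * dt))
  PreL <- c(0, cumsum(exp(Lpre[1 + seq_len(K0)]) * dt))

  mid <- numeric(n); Sa <- numeric(n)        # integral to te_{a_i}..; S^{-i} there
  cens_part <- PreM[a_i + 1L]
  Sa <- exp(Mpre[a_i + 1L])
  if (any(own)) {
    # event subjects: own factor replaces M at k_i = a_i
    ai <- a_i[own]
    Sown <- exp(Mpre[ai] + o_i[own])
    cens_part[own] <- PreM[ai] + Sown * dt[ai]
    Sa[own] <- Sown
  }
  mid <- cens_part
  tail <- ifelse(a_i < K0,
                 Sa * (PreL[K0 + 1L] - PreL[a_i + 1L]) / exp(Lpre[a_i + 1L]),
                 0)
  theta_i <- lead + mid + tail
  n * theta - (n - 1) * theta_i
}

# ---- IPCW (covariate-adjusted) pseudo-values -------------------------------
ipcw_pseudo <- function(time, event, functional, t0, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(time)
  cens <- 1 - event
  G <- tryCatch({
    if (sum(cens) == 0) {
      rep(1, n)                               # no censoring: weights are unity
    } else {
      cf <- survival::coxph(survival::Surv(time, cens) ~ .,
                            data = covariates, ties = "efron")
      if (any(!is.finite(coef(cf)))) stop("censoring model did not converge")
      bh <- survival::basehaz(cf, centered = FALSE)
      lp <- predict(cf, newdata = covariates, type = "risk", reference = "zero")
      # G(T_i - | x_i): baseline cumulative hazard left-limit at T_i
      H0 <- c(0, bh$hazard)[findInterval(time, bh$time, left.open = TRUE) + 1L]
      exp(-H0 * lp)
    }
  }, error = function(e) {
    warning("censoring model failed (", conditionMessage(e),
            "); falling back to jackknife pseudo-observations")
    NULL
  })
  if (is.null(G))
    return(structure(jackknife_pseudo(time, event, functional, t0, FALSE),
                     method = "jackknife_fallback"))
  G <- pmax(G, 0.05)                          # positivity guard

  if (functional == "rmst") {
    # theta = t0 - E[(t0 - T)+]; IPCW estimate is a weighted mean, so the
    # jackknife has the closed form t0 - A_i
    A <- event * pmax(t0 - time, 0) / G
    return(t0 - A)
  }
  # cumhaz: theta = -log(1 - F(t0)), F IPCW-estimated
  B <- event * (time <= t0) / G
  eps <- 1 / (2 * n)
  Fh <- mean(B)
  theta <- -log(max(1 - Fh, eps))
  F_i <- (sum(B) - B) / (n - 1)
  theta_i <- -log(pmax(1 - F_i, eps))
  n * theta - (n - 1) * theta_i
}

#' Pseudo-outcome vector for a two-arm cohort
#'
#' Convenience wrapper constructing the pseudo-observation response used by
#' the strategy ensemble: by default pseudo-values are built within each
#' treatment arm (separate Kaplan-Meier curves, matching per-arm outcome
#' modelling), or from the pooled sample with `pool = TRUE`.
#'
#' @param data cohort data.frame with `time_years`, `event` and an arm column.
#' @param arm_col name of the treatment column (two levels).
#' @param functional,t0,method,covariate_cols passed to
#'   [pseudo_observations()]; `covariate_cols` names the baseline covariates
#'   used by the covariate-adjusted method.
#' @param pool build pseudo-values from the pooled sample instead of per arm.
#' @return numeric vector aligned with `data` rows.
#' @export
build_pseudo <- function(data, arm_col = "arm", functional = "rmst", t0 = 3.2,
                         method = "jackknife", covariate_cols = NULL,
                         pool = FALSE) {
  covs <- if (!is.null(covariate_cols))
    data[, covariate_cols, drop = FALSE] else NULL
  if (pool) {
    y <- pseudo_observations(data$time_years, data$event, functional, t0,
                             method, covariates = covs)
    return(as.numeric(y))
  }
  y <- numeric(nrow(data))
  for (a in unique(data[[arm_col]])) {
    sel <- data[[arm_col]] == a
    y[sel] <- as.numeric(pseudo_observations(
      data$time_years[sel], data$event[sel], functional, t0, method,
      covariates = if (!is.null(covs)) covs[sel, , drop = FALSE] else NULL))
  }
  y
}
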