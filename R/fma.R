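# ---- single-strategy engine ------------------------------------------------
# Trains one strategy on a training set and returns a factual-prediction
# closure plus the strategy's full-data fit; this is the unit both the
# cross-validation loop and the ATE computation reuse.
train_strategy <- function(spec, data, pseudo, covnames, functional, t0) {
  covs <- data[, covnames, drop = FALSE]
  trt <- data$.trt
  if (spec$treatment_model == "none" && spec$outcome_model == "none") {
    mu0 <- mean(pseudo[trt == 0]); mu1 <- mean(pseudo[trt == 1])
    return(list(
      predict = function(newcovs, newtrt) ifelse(newtrt == 1, mu1, mu0),
      fit = strategy_fit(ate = estimand_from_means(mu0, mu1, functional),
                         factual = ifelse(trt == 1, mu1, mu0),
                         m0 = rep(mu0, nrow(data)), m1 = rep(mu1, nrow(data)))))
  }
  if (spec$outcome_model != "none") {
    pr <- outcome_fitter(spec, cbind(data, .y = pseudo), covnames,
                         functional, t0)
    m0 <- pr(covs, rep(0, nrow(covs)))
    m1 <- pr(covs, rep(1, nrow(covs)))
    return(list(
      predict = pr,
      fit = strategy_fit(ate = estimand_from_means(mean(m0), mean(m1),
                                                   functional),
                         factual = ifelse(trt == 1, m1, m0),
                         m0 = m0, m1 = m1)))
  }
  # propensity-based adjustment
  ps_fit <- propensity_fitter(spec, covs, trt)
  scores <- clip_scores(ps_fit(covs))
  hp <- spec$hyperparameters
  fit <- switch(spec$adjustment,
    ipw = ipw_ate(pseudo, scores, trt, functional),
    stratification = stratified_ate(pseudo, scores, trt, functional,
                                    n_strata = hp$n_strata %||% 5),
    matching = matched_ate(pseudo, scores, trt, functional,
                           caliper_sd = hp$caliper_sd %||% 0.2),
    stop("strategy '", spec$name, "' has a treatment model but no adjustment"))
  predict_fun <- if (spec$adjustment == "stratification") {
    info <- fit$info
    mu_of <- function(str_orig, arm) {
      merged <- info$map[pmin(pmax(str_orig, 1L), length(info$map))]
      info$mu[match(merged, info$levels), arm + 1L]
    }
    function(newcovs, newtrt) {
      sc <- clip_scores(ps_fit(newcovs))
      str_orig <- findInterval(sc, info$breaks, all.inside = TRUE)
      mu_of(str_orig, newtrt)
    }
  } else {
    mu0 <- fit$m0[1]; mu1 <- fit$m1[1]
    function(newcovs, newtrt) ifelse(newtrt == 1, mu1, mu0)
  }
  list(predict = predict_fun, fit = fit)
}

#' Cross-validated factual predictions for one strategy
#'
#' K-fold approximation to leave-one-out: folds are stratified by arm, the
#' strategy (both its treatment and outcome components) is refit on each
#' fold's complement, and held-out patients are predicted under their factual
#' arm. `n_folds = n` gives exact leave-one-out.
#'
#' @param spec a [strategy_spec()].
#' @param data engine data.frame (columns `.trt`, `time_years`, `event`,
#'   covariates).
#' @param pseudo pseudo-outcome vector aligned with `data`.
#' @param covnames covariate column names.
#' @param functional,t0 estimand scale and cut-off.
#' @param n_folds number of folds (>= 2).
#' @return numeric vector of out-of-fold factual predictions.
#' @export
crossval_factual_predictions <- function(spec, data, pseudo, covnames,
                                         functional, t0, n_folds = 10) {
  n <- nrow(data)
  stopifnot(n_folds >= 2)
  folds <- make_folds(data$.trt, min(n_folds, n))
  pred <- numeric(n)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    tr <- train_strategy(spec, data[!hold, , drop = FALSE], pseudo[!hold],
                         covnames, functional, t0)
    pred[hold] <- tr$predict(data[hold, covnames, drop = FALSE],
                             data$.trt[hold])
  }
  pred
}

# arm-stratified fold assignment; every fold sees both arms when possible
make_folds <- function(trt, k) {
  folds <- integer(length(trt))
  for (a in unique(trt)) {
    idx <- which(trt == a)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated mean squared prediction error
#'
#' `CvMSPE(S) = (N0 + N1)^-1 * sum_i (Y_i - mhat_S^(-i)(T_i, x_i))^2`: the
#' average squared distance between each patient's (pseudo-)outcome and the
#' strategy's cross-validated prediction under the patient's factual arm.
#' Larger values indicate poorer support for the strategy from the data.
#'
#' @param pseudo (pseudo-)outcome vector `Y_i`.
#' @param predictions cross-validated factual predictions, same length.
#' @return nonnegative scalar.
#' @export
#' @examples
#' cvmspe(c(1, 2, 3, 4), c(1, 2, 2, 5))  # 0.5
cvmspe <- function(pseudo, predictions) {
  if (length(pseudo) != length(predictions))
    stop("pseudo and predictions must be aligned")
  mean((pseudo - predictions)^2)
}

#' Support weights from CvMSPE scores
#'
#' Maps strategy scores to normalized weights. The default `"softmax"` rule is
#' `w_S` proportional to `exp(-N * (CvMSPE_S - min CvMSPE) / (2 * sigma2))`
#' with `sigma2 = min CvMSPE`: equal scores get uniform weights, the weights
#' are monotone non-increasing in CvMSPE, and as `N` grows the rule approaches
#' best-model selection. Alternatives: `"inverse"` (proportional to
#' 1/CvMSPE) and `"best"` (all weight on the minimum).
#'
#' @param scores vector of CvMSPE values (finite, >= 0).
#' @param n total sample size `N = N0 + N1` (softmax rule).
#' @param rule `"softmax"`, `"inverse"` or `"best"`.
#' @return weights summing to 1.
#' @export
fma_weights <- function(scores, n, rule = c("softmax", "inverse", "best")) {
  rule <- match.arg(rule)
  if (!length(scores)) stop("empty strategy roster")
  if (any(!is.finite(scores) | scores < 0))
    stop("CvMSPE scores must be finite and nonnegative")
  w <- switch(rule,
    softmax = {
      s2 <- max(min(scores), .Machine$double.eps)
      exp(-n * (scores - min(scores)) / (2 * s2))
    },
    inverse = 1 / pmax(scores, .Machine$double.eps),
    best = as.numeric(scores == min(scores)))
  w / sum(w)
}

#' Combine strategy ATEs into the model-averaged estimate
#'
#' Weighted mean of the per-strategy ATE estimates; ratio estimands
#' (restricted hazard ratio, odds ratio) are averaged on the log scale and
#' exponentiated. Also identifies the best model (minimum CvMSPE).
#'
#' @param ates per-strategy ATE estimates.
#' @param weights normalized weights (same order).
#' @param functional `"rmst"`, `"cumhaz"` or `"binary"`.
#' @return the FMA ATE estimate.
#' @export
fma_estimate <- function(ates, weights, functional) {
  stopifnot(length(ates) == length(weights), length(ates) > 0)
  if (estimand_is_ratio(functional)) exp(sum(weights * log(ates)))
  else sum(weights * ates)
}

# ---- the fitting function --------------------------------------------------

#' Frequentist model-averaged treatment-effect estimate for a cohort pair
#'
#' Fits the full pipeline on a two-arm cohort: builds pseudo-observations of
#' the chosen survival functional (or the binary event-by-`t0` indicator),
#' scores every roster strategy by cross-validated mean squared prediction
#' error (CvMSPE), converts scores to support weights, and combines the
#' per-strategy ATE estimates into the model-averaged estimate, optionally
#' with a percentile-bootstrap confidence interval (patients resampled with
#' replacement within arm; the entire pipeline is rerun per replicate).
#'
#' @param formula `Surv(time, event) ~ treatment + covariates`; the treatment
#'   variable is named by `treatment` (default: first right-hand-side term).
#' @param data the cohort data.frame (one row per patient).
#' @param treatment name of the treatment column.
#' @param arms length-2 character vector: reference arm, comparator arm
#'   (default: the treatment factor's first two levels). Other rows dropped.
#' @param estimand `"rhr"` (restricted hazard ratio), `"rmst_diff"`, or
#'   `"odds_ratio"` (binary event-by-`t0`; restricted to patients with an
#'   event or follow-up beyond `t0`).
#' @param t0 cut-off in years (default 3.2).
#' @param roster list of [strategy_spec()]s; defaults to [default_roster()].
#' @param n_folds cross-validation folds (default 10).
#' @param n_bootstrap bootstrap replicates for the 95% CI (default 500; 0
#'   skips the CI).
#' @param pseudo_method `"jackknife"` or `"covariate_adjusted"`.
#' @param pool_pseudo build pseudo-values from the pooled sample instead of
#'   per arm.
#' @param weight_rule passed to [fma_weights()].
#' @param impute impute missing region to the mode first (see
#'   [impute_region()]).
#' @param seed integer seed governing folds, tree methods and the bootstrap.
#' @return an object of class `fma`; see [print.fma()], [summary.fma()],
#'   [coef.fma()], [confint.fma()], [plot.fma()].
#' @export
#' @examples
#' cfg <- sim_config(n_per_arm = c(a = 150, b = 150),
#'                   covariates = list(x = list(type = "continuous",
#'                                              mean = 0, sd = 1)),
#'                   outcome = list(family = "exponential", rate = 0.1,
#'                                  log_hr = list(b = log(0.7))),
#'                   seed = 2)
#' coh <- simulate_cohort(cfg)
#' fit <- fma(survival::Surv(time_years, event) ~ arm + x, coh,
#'            roster = reduced_roster(), n_folds = 5, n_bootstrap = 0)
#' fit
fma <- function(formula, data, treatment = NULL, arms = NULL,
                estimand = c("rhr", "rmst_diff", "odds_ratio"),
                t0 = 3.2, roster = default_roster(), n_folds = 10,
                n_bootstrap = 500,
                pseudo_method = c("jackknife", "covariate_adjusted"),
                pool_pseudo = FALSE,
                weight_rule = "softmax", impute = TRUE, seed = 1L) {
  estimand <- match.arg(estimand)
  pseudo_method <- match.arg(pseudo_method)
  cl <- match.call()

  tm <- terms(formula, data = data)
  vars <- all.vars(formula)
  lhs <- all.vars(formula[[2]])
  time_col <- lhs[1]; event_col <- lhs[2]
  rhs <- attr(tm, "term.labels")
  if (is.null(treatment)) treatment <- rhs[1]
  covnames <- setdiff(rhs, treatment)
  if (!treatment %in% names(data)) stop("treatment column '", treatment,
                                        "' not found")
  trt_raw <- as.factor(data[[treatment]])
  if (is.null(arms)) arms <- levels(trt_raw)[1:2]
  missing_arm <- setdiff(arms, levels(droplevels(trt_raw)))
  if (length(missing_arm))
    stop("arm '", missing_arm[1], "' not present in the data")

  d <- data[trt_raw %in% arms, , drop = FALSE]
  if (impute && "region" %in% names(d)) d <- impute_region(d)
  d$.trt <- as.integer(as.character(d[[treatment]]) == arms[2])
  d$time_years <- d[[time_col]]
  d$event <- d[[event_col]]
  functional <- switch(estimand, rhr = "cumhaz", rmst_diff = "rmst",
                       odds_ratio = "binary")
  if (estimand == "odds_ratio") {
    keep <- d$event == 1 & d$time_years <= t0 | d$time_years >= t0
    d <- d[keep, , drop = FALSE]
  }
  n0 <- sum(d$.trt == 0); n1 <- sum(d$.trt == 1)
  if (n0 < 2 || n1 < 2) stop("need at least 2 patients per arm")

  set.seed(seed)
  core <- fma_core(d, covnames, functional, t0, roster, n_folds,
                   pseudo_method, pool_pseudo, weight_rule)

  ci <- c(NA_real_, NA_real_)
  boot_est <- numeric(0)
  if (n_bootstrap > 0) {
    boot_est <- rep(NA_real_, n_bootstrap)
    i0 <- which(d$.trt == 0); i1 <- which(d$.trt == 1)
    for (b in seq_len(n_bootstrap)) {
      idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
      boot_est[b] <- tryCatch(
        fma_core(d[idx, , drop = FALSE], covnames, functional, t0, roster,
                 n_folds, pseudo_method, pool_pseudo, weight_rule)$fma_ate,
        error = function(e) NA_real_)
    }
    fail_rate <- mean(is.na(boot_est))
    if (fail_rate > 0.2)
      stop(sprintf("bootstrap replicate failure rate %.0f%% exceeds 20%%",
                   100 * fail_rate))
    ci <- unname(quantile(boot_est, c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(estimand = estimand, functional = functional, t0 = t0,
                 arms = arms, n0 = n0, n1 = n1,
                 fma_ate = core$fma_ate,
                 best_model = core$best_model,
                 per_strategy = core$per_strategy,
                 failed = core$failed,
                 ci_lower = ci[1], ci_upper = ci[2],
                 bootstrap = boot_est,
                 metadata = list(seed = seed, n_folds = n_folds,
                                 n_bootstrap = n_bootstrap,
                                 pseudo_method = core$pseudo_method,
                                 pool_pseudo = pool_pseudo,
                                 weight_rule = weight_rule),
                 call = cl),
            class = "fma")
}

# one full pipeline pass on an engine-ready data.frame (column .trt etc.)
fma_core <- function(d, covnames, functional, t0, roster, n_folds,
                     pseudo_method, pool_pseudo, weight_rule) {
  pm <- pseudo_method
  if (functional == "binary") {
    Y <- as.numeric(d$event == 1 & d$time_years <= t0)
    pm <- "none"
  } else {
    Y <- build_pseudo(d, arm_col = ".trt", functional = functional, t0 = t0,
                      method = pseudo_method, covariate_cols = covnames,
                      pool = pool_pseudo)
  }
  fits <- list(); cvs <- numeric(0); ates <- numeric(0); failed <- character(0)
  for (spec in roster) {
    res <- tryCatch({
      tr <- train_strategy(spec, d, Y, covnames, functional, t0)
      cvp <- crossval_factual_predictions(spec, d, Y, covnames, functional,
                                          t0, n_folds)
      list(fit = tr$fit, cv = cvmspe(Y, cvp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s: %s", spec$name, conditionMessage(res)))
      next
    }
    fits[[spec$name]] <- res$fit
    cvs <- c(cvs, setNames(res$cv, spec$name))
    ates <- c(ates, setNames(res$fit$ate, spec$name))
  }
  if (!length(fits)) stop("all strategies failed: ",
                          paste(failed, collapse = "; "))
  w <- fma_weights(cvs, n = nrow(d), rule = weight_rule)
  best <- names(cvs)[which.min(cvs)]
  per_strategy <- data.frame(strategy = names(cvs), ate = unname(ates),
                             cvmspe = unname(cvs), weight = unname(w),
                             stringsAsFactors = FALSE, row.names = NULL)
  list(fma_ate = fma_estimate(ates, w, functional),
       best_model = list(strategy = best, ate = unname(ates[best])),
       per_strategy = per_strategy, failed = failed, fits = fits,
       pseudo_method = pm)
}

# ---- methods ---------------------------------------------------------------

estimand_label <- function(x)
  switch(x$estimand,
         rhr = sprintf("restricted hazard ratio at %.3g years", x$t0),
         rmst_diff = sprintf("RMST difference at %.3g years (years)", x$t0),
         odds_ratio = sprintf("odds ratio of event by %.3g years", x$t0))

#' @method print fma
#' @export
print.fma <- function(x, digits = 3, ...) {
  cat("Frequentist model-averaged ATE:", x$arms[2], "vs", x$arms[1],
      sprintf("(n = %d / %d)\n", x$n1, x$n0))
  cat("Estimand:", estimand_label(x), "\n")
  cat(sprintf("FMA estimate: %.*f", digits, x$fma_ate))
  if (!is.na(x$ci_lower))
    cat(sprintf("  [95%% CI %.*f, %.*f]", digits, x$ci_lower,
                digits, x$ci_upper))
  cat("\n")
  cat(sprintf("Best model (min CvMSPE): %s, ATE %.*f\n",
              x$best_model$strategy, digits, x$best_model$ate))
  cat(length(x$per_strategy$strategy), "strategies scored")
  if (length(x$failed)) cat(";", length(x$failed), "failed")
  cat("\n")
  invisible(x)
}

#' @method summary fma
#' @export
summary.fma <- function(object, ...) {
  structure(list(fit = object), class = "summary.fma")
}

#' @method print summary.fma
#' @export
print.summary.fma <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-strategy results:\n")
  tab <- x$fit$per_strategy
  tab$ate <- round(tab$ate, digits)
  tab$cvmspe <- signif(tab$cvmspe, digits + 2)
  tab$weight <- round(tab$weight, digits + 1)
  print(tab[order(tab$cvmspe), ], row.names = FALSE)
  if (length(x$fit$failed))
    cat("\nFailed strategies:\n ", paste(x$fit$failed, collapse = "\n  "), "\n")
  invisible(x)
}

#' @method coef fma
#' @export
coef.fma <- function(object, ...) {
  setNames(c(object$fma_ate, object$best_model$ate),
           c("fma", "best_model"))
}

#' @method confint fma
#' @export
confint.fma <- function(object, parm, level = 0.95, ...) {
  if (!length(object$bootstrap))
    stop("no bootstrap replicates stored; refit with n_bootstrap > 0")
  a <- (1 - level) / 2
  ci <- quantile(object$bootstrap, c(a, 1 - a), na.rm = TRUE)
  out <- matrix(ci, 1, 2,
                dimnames = list("fma", sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' Forest plot of strategy and model-averaged estimates
#'
#' Per-strategy ATE estimates ordered by CvMSPE, with the model-averaged and
#' best-model estimates below and the estimand's null value as a reference
#' line (base graphics).
#'
#' @param x an [fma()] fit.
#' @param ... passed to [graphics::plot()].
#' @method plot fma
#' @export
plot.fma <- function(x, ...) {
  tab <- x$per_strategy[order(x$per_strategy$cvmspe, decreasing = TRUE), ]
  est <- c(x$fma_ate, tab$ate)
  labs <- c("FMA", tab$strategy)
  ylim <- c(0.5, length(est) + 0.5)
  log_axis <- estimand_is_ratio(x$functional)
  graphics::plot(est, seq_along(est), yaxt = "n", ylab = "",
                 xlab = estimand_label(x), ylim = ylim,
                 log = if (log_axis) "x" else "",
                 pch = c(18, rep(19, nrow(tab))),
                 cex = c(1.6, rep(1, nrow(tab))), ...)
  graphics::axis(2, at = seq_along(est), labels = labs, las = 1, cex.axis = 0.7)
  graphics::abline(v = estimand_null(x$functional), lty = 2, col = "grey40")
  invisible(x)
}

#' Tabulate a set of model-averaged analyses
#'
#' Combines several [fma()] fits (e.g. one per outcome and cohort pair) into
#' a single forest-style table, optionally writing CSV and JSON reports.
#'
#' @param results named list of `fma` objects.
#' @param file optional path prefix; writes `<file>.csv` and `<file>.json`.
#' @return data.frame with one row per analysis.
#' @export
report_forest <- function(results, file = NULL) {
  stopifnot(length(results) > 0)
  if (is.null(names(results)))
    names(results) <- paste0("analysis_", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(analysis = nm, estimand = r$estimand, t0 = r$t0,
               reference = r$arms[1], comparator = r$arms[2],
               n0 = r$n0, n1 = r$n1,
               estimate = r$fma_ate, ci_lower = r$ci_lower,
               ci_upper = r$ci_upper,
               best_model = r$best_model$strategy,
               best_model_ate = r$best_model$ate,
               n_strategies = nrow(r$per_strategy),
               n_failed = length(r$failed),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.csv(tab, paste0(file, ".csv"), row.names = FALSE)
    detail <- lapply(results, function(r)
      list(estimand = r$estimand, t0 = r$t0, arms = r$arms,
           n0 = r$n0, n1 = r$n1, estimate = r$fma_ate,
           ci = c(r$ci_lower, r$ci_upper), best_model = r$best_model,
           per_strategy = r$per_strategy, failed = r$failed,
           metadata = r$metadata))
    jsonlite::write_json(detail, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  tab
}
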