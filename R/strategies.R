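#' Specify a single analysis strategy
#'
#' A strategy combines an optional treatment (propensity) model, an
#' adjustment mechanism, and an optional outcome model. The roster of such
#' strategies is what the model-averaging engine scores and combines.
#'
#' The degenerate all-`"none"` strategy is allowed under the reserved name
#' `"unadjusted"`: it predicts each arm's mean pseudo-outcome and its ATE is
#' the raw arm contrast. Every other strategy must have at least one
#' component, and any adjustment requires a treatment model.
#'
#' @param name identifier (unique within a roster).
#' @param treatment_model `"none"`, `"logistic"`, `"logistic_stepwise"`,
#'   `"logistic_penalised"`, `"random_forest"` or `"gradient_boosting"`.
#' @param adjustment `"none"`, `"ipw"`, `"matching"` or `"stratification"`.
#' @param outcome_model `"none"`, `"cox_main_effects"`, `"cox_two_way"`,
#'   `"parametric_survival"`, `"penalised_cox"`, `"random_forest"` or
#'   `"gradient_boosting"`.
#' @param per_arm fit the outcome model separately by treatment arm.
#' @param hyperparameters named list (entry/stay alpha for stepwise, elastic
#'   net mixing `alpha`, tree depth / rounds, `n_strata`, `caliper_sd`,
#'   `trt_interactions`...).
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          treatment_model = "none",
                          adjustment = "none",
                          outcome_model = "none",
                          per_arm = FALSE,
                          hyperparameters = list()) {
  treatment_model <- match.arg(treatment_model,
    c("none", "logistic", "logistic_stepwise", "logistic_penalised",
      "random_forest", "gradient_boosting"))
  adjustment <- match.arg(adjustment,
    c("none", "ipw", "matching", "stratification"))
  outcome_model <- match.arg(outcome_model,
    c("none", "cox_main_effects", "cox_two_way", "parametric_survival",
      "penalised_cox", "random_forest", "gradient_boosting"))
  if (adjustment != "none" && treatment_model == "none")
    stop("adjustment '", adjustment, "' requires a treatment model")
  if (treatment_model == "none" && outcome_model == "none" &&
      !identical(name, "unadjusted"))
    stop("at least one of treatment_model/outcome_model must be set ",
         "(use name = 'unadjusted' for the raw arm contrast)")
  structure(list(name = name, treatment_model = treatment_model,
                 adjustment = adjustment, outcome_model = outcome_model,
                 per_arm = per_arm, hyperparameters = hyperparameters),
            class = "strategy_spec")
}

#' Default and reduced strategy rosters
#'
#' `default_roster()` mirrors a full ensemble: the unadjusted contrast;
#' IPW, matching and stratification on stepwise / penalised logistic, random
#' forest and gradient-boosted propensity scores; Cox models with main
#' effects and with all two-way interactions, with and without penalisation,
#' pooled and per arm; a parametric (Weibull) survival model; and random
#' forest / gradient boosting outcome regressions on the pseudo-outcome
#' scale. `reduced_roster()` is a four-strategy subset (unadjusted,
#' IPW-logistic, Cox main effects, gradient-boosting outcome) for
#' simulation studies where runtime matters.
#'
#' @return list of [strategy_spec()] objects.
#' @export
default_roster <- function() {
  list(
    strategy_spec("unadjusted"),
    strategy_spec("ipw_logistic_stepwise", "logistic_stepwise", "ipw"),
    strategy_spec("ipw_logistic_penalised", "logistic_penalised", "ipw"),
    strategy_spec("ipw_random_forest", "random_forest", "ipw"),
    strategy_spec("ipw_xgb", "gradient_boosting", "ipw"),
    strategy_spec("match_logistic", "logistic_stepwise", "matching"),
    strategy_spec("strat_logistic", "logistic_stepwise", "stratification"),
    strategy_spec("cox_me", outcome_model = "cox_main_effects"),
    strategy_spec("cox_2way", outcome_model = "cox_two_way"),
    strategy_spec("cox_penalised", outcome_model = "penalised_cox"),
    strategy_spec("weibull", outcome_model = "parametric_survival"),
    strategy_spec("cox_me_per_arm", outcome_model = "cox_main_effects",
                  per_arm = TRUE),
    strategy_spec("rf_outcome", outcome_model = "random_forest"),
    strategy_spec("xgb_outcome", outcome_model = "gradient_boosting")
  )
}

#' @rdname default_roster
#' @export
reduced_roster <- function() {
  list(
    strategy_spec("unadjusted"),
    strategy_spec("ipw_logistic", "logistic", "ipw"),
    strategy_spec("cox_me", outcome_model = "cox_main_effects"),
    strategy_spec("xgb_outcome", outcome_model = "gradient_boosting")
  )
}

# ---- propensity -----------------------------------------------------------

#' Fit a propensity model and return per-patient scores
#'
#' Two-arm propensity scores P(T = 1 | x), clipped to `[0.01, 0.99]` as
#' positivity protection. Stepwise logistic uses forward selection with a
#' chi-square entry threshold (alpha 0.05 by default); penalised logistic is
#' an elastic net with internally cross-validated penalty; the tree methods
#' are a probability forest and gradient boosting with conventional defaults
#' (all hyperparameters overridable through the strategy spec). Randomness
#' (CV folds, forests, boosting) is governed by the caller's RNG state.
#'
#' @param spec a [strategy_spec()] with `treatment_model != "none"`.
#' @param covariates baseline covariate data.frame.
#' @param treatment 0/1 vector.
#' @return numeric scores in (0, 1).
#' @export
fit_propensity <- function(spec, covariates, treatment) {
  stopifnot(spec$treatment_model != "none", all(treatment %in% c(0, 1)))
  covariates <- as.data.frame(covariates)
  fitter <- propensity_fitter(spec, covariates, treatment)
  clip_scores(fitter(covariates))
}

clip_scores <- function(p) pmin(pmax(p, 0.01), 0.99)

# glmnet requires >= 2 predictor columns; pad with a zero column when needed
pad_design <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, .pad = rep(0, nrow(X)))
}

# returns a closure newdata -> score, trained on (covariates, treatment)
propensity_fitter <- function(spec, covariates, treatment) {
  hp <- spec$hyperparameters
  df <- data.frame(.trt = treatment, covariates, check.names = TRUE)
  switch(spec$treatment_model,
    logistic = {
      fit <- suppressWarnings(glm(.trt ~ ., data = df, family = binomial()))
      function(nd) predict(fit, newdata = data.frame(nd, check.names = TRUE),
                           type = "response")
    },
    logistic_stepwise = {
      alpha <- hp$alpha_enter %||% 0.05
      null <- suppressWarnings(glm(.trt ~ 1, data = df, family = binomial()))
      full <- reformulate(names(covariates), response = ".trt")
      fit <- suppressWarnings(step(null, scope = list(lower = ~1, upper = full),
                                   direction = "both",
                                   k = qchisq(1 - alpha, 1), trace = 0))
      function(nd) predict(fit, newdata = data.frame(nd, check.names = TRUE),
                           type = "response")
    },
    logistic_penalised = {
      X <- pad_design(model.matrix(~ ., covariates)[, -1, drop = FALSE])
      fit <- glmnet::cv.glmnet(X, treatment, family = "binomial",
                               alpha = hp$alpha %||% 0.5,
                               nfolds = hp$nfolds %||% 5)
      function(nd) {
        Xn <- pad_design(model.matrix(~ ., as.data.frame(nd))[, -1,
                                                              drop = FALSE])
        drop(predict(fit, newx = Xn, s = "lambda.min", type = "response"))
      }
    },
    random_forest = {
      fit <- ranger::ranger(y = factor(treatment), x = covariates,
                            probability = TRUE,
                            num.trees = hp$num_trees %||% 300,
                            min.node.size = hp$min_node_size %||% 20,
                            seed = sample.int(.Machine$integer.max, 1),
                            num.threads = 1)
      function(nd) predict(fit, data = as.data.frame(nd),
                           num.threads = 1)$predictions[, "1"]
    },
    gradient_boosting = {
      X <- model.matrix(~ ., covariates)[, -1, drop = FALSE]
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth %||% 3,
                      eta = hp$eta %||% 0.1, nthread = 1,
                      seed = sample.int(.Machine$integer.max, 1)),
        data = xgboost::xgb.DMatrix(X, label = treatment, nthread = 1),
        nrounds = hp$nrounds %||% 100, verbose = 0)
      function(nd) {
        Xn <- model.matrix(~ ., as.data.frame(nd))[, -1, drop = FALSE]
        predict(fit, xgboost::xgb.DMatrix(Xn, nthread = 1))
      }
    })
}

# ---- adjustment estimators -------------------------------------------------

# Hajek weights with truncation at the 99th percentile
hajek_weights <- function(scores, treatment, truncate = 0.99) {
  w <- treatment / scores + (1 - treatment) / (1 - scores)
  cap <- quantile(w, truncate)
  pmin(w, cap)
}

#' Inverse-probability-weighted ATE from pseudo-outcomes
#'
#' Normalized (Hajek) weighting: each arm's counterfactual mean is the
#' weighted mean of pseudo-outcomes with weights `T/e + (1-T)/(1-e)`,
#' truncated at their 99th percentile.
#'
#' @param pseudo pseudo-outcome vector.
#' @param scores propensity scores in (0, 1).
#' @param treatment 0/1 vector.
#' @param functional `"rmst"`, `"cumhaz"` or `"binary"` (sets the estimand).
#' @return a `strategy_fit` list: `ate`, per-patient `factual`,
#'   counterfactual `m0`/`m1`, `propensity`.
#' @export
ipw_ate <- function(pseudo, scores, treatment, functional) {
  stopifnot(all(scores > 0 & scores < 1))
  w <- hajek_weights(scores, treatment)
  mean0 <- weighted.mean(pseudo[treatment == 0], w[treatment == 0])
  mean1 <- weighted.mean(pseudo[treatment == 1], w[treatment == 1])
  n <- length(pseudo)
  strategy_fit(ate = estimand_from_means(mean0, mean1, functional),
               factual = ifelse(treatment == 1, mean1, mean0),
               m0 = rep(mean0, n), m1 = rep(mean1, n),
               propensity = scores)
}

#' Propensity-stratified ATE
#'
#' Patients are cut into quantile strata on the propensity score (5 by
#' default); within-stratum arm means are combined with stratum-size (ATE)
#' weights. Strata lacking one arm are merged with the neighbouring stratum.
#'
#' @inheritParams ipw_ate
#' @param n_strata number of quantile strata.
#' @return a `strategy_fit` (factual predictions are stratum-arm means).
#' @export
stratified_ate <- function(pseudo, scores, treatment, functional,
                           n_strata = 5) {
  qs <- unique(quantile(scores, probs = seq(0, 1, length.out = n_strata + 1)))
  n_orig <- max(length(qs) - 1L, 1L)
  stratum <- if (length(qs) <= 2) rep(1L, length(scores)) else
    cut(scores, qs, include.lowest = TRUE, labels = FALSE)
  map <- seq_len(n_orig)                     # original stratum -> merged label
  # merge strata missing an arm into the neighbour below (or above for the first)
  repeat {
    tab <- table(factor(stratum), factor(treatment, levels = c(0, 1)))
    bad <- which(tab[, 1] == 0 | tab[, 2] == 0)
    if (!length(bad)) break
    if (nrow(tab) < 2) stop("fewer than 2 usable strata: no arm overlap")
    lv <- sort(unique(stratum))
    b <- lv[bad[1]]
    target <- if (b == lv[1]) lv[2] else lv[which(lv == b) - 1]
    stratum[stratum == b] <- target
    map[map == b] <- target
  }
  lv <- sort(unique(stratum))
  n <- length(pseudo)
  m0 <- m1 <- numeric(n); w_s <- numeric(length(lv))
  mu <- matrix(NA_real_, length(lv), 2)
  for (j in seq_along(lv)) {
    s <- stratum == lv[j]
    mu[j, 1] <- mean(pseudo[s & treatment == 0])
    mu[j, 2] <- mean(pseudo[s & treatment == 1])
    w_s[j] <- mean(s)
    m0[s] <- mu[j, 1]; m1[s] <- mu[j, 2]
  }
  mean0 <- sum(w_s * mu[, 1]); mean1 <- sum(w_s * mu[, 2])
  strategy_fit(ate = estimand_from_means(mean0, mean1, functional),
               factual = ifelse(treatment == 1, m1, m0),
               m0 = m0, m1 = m1, propensity = scores,
               info = list(n_strata_used = length(lv), breaks = qs,
                           map = map, levels = lv, mu = mu))
}

#' Propensity-matched ATE
#'
#' 1:1 nearest-neighbour matching on the logit propensity score, without
#' replacement, caliper `caliper_sd` standard deviations of the logit score
#' (0.2 by default), treated units processed in random order (governed by the
#' caller's RNG state). The ATE is the arm contrast within the matched set.
#'
#' @inheritParams ipw_ate
#' @param caliper_sd caliper width in SDs of the logit score.
#' @return a `strategy_fit`; `info$n_matched` pairs, `info$unmatched` treated
#'   left unmatched.
#' @export
matched_ate <- function(pseudo, scores, treatment, functional,
                        caliper_sd = 0.2) {
  lo <- qlogis(scores)
  caliper <- caliper_sd * sd(lo)
  tr <- which(treatment == 1); ct <- which(treatment == 0)
  if (!length(tr) || !length(ct)) stop("both arms required for matching")
  ord <- sample(tr)
  used <- logical(length(ct))
  pairs_t <- integer(0); pairs_c <- integer(0)
  for (i in ord) {
    dist <- abs(lo[ct] - lo[i])
    dist[used] <- Inf
    j <- which.min(dist)
    if (is.finite(dist[j]) && dist[j] <= caliper) {
      used[j] <- TRUE
      pairs_t <- c(pairs_t, i); pairs_c <- c(pairs_c, ct[j])
    }
  }
  if (!length(pairs_t)) stop("zero matches within caliper")
  mean0 <- mean(pseudo[pairs_c]); mean1 <- mean(pseudo[pairs_t])
  n <- length(pseudo)
  strategy_fit(ate = estimand_from_means(mean0, mean1, functional),
               factual = ifelse(treatment == 1, mean1, mean0),
               m0 = rep(mean0, n), m1 = rep(mean1, n), propensity = scores,
               info = list(n_matched = length(pairs_t),
                           unmatched = length(tr) - length(pairs_t)))
}

strategy_fit <- function(ate, factual, m0, m1, propensity = NULL,
                         info = list()) {
  structure(list(ate = ate, factual = factual, m0 = m0, m1 = m1,
                 propensity = propensity, info = info),
            class = "strategy_fit")
}

# ---- covariate balance -----------------------------------------------------

w_mean <- function(x, w) sum(w * x) / sum(w)
w_var <- function(x, w) {
  m <- w_mean(x, w)
  sum(w * (x - m)^2) / sum(w) * length(x) / max(length(x) - 1, 1)
}

#' Covariate balance diagnostics
#'
#' Standardized differences, variance ratios and their scalar summary ASAM
#' (average standardized absolute mean difference). Continuous covariates use
#' `d = (x1 - x0) / sqrt((s1^2 + s0^2) / 2)`; binary (0/1) columns use the
#' proportion-based denominator `sqrt((p1(1-p1) + p0(1-p0)) / 2)`. Weighted
#' versions use weighted moments. Conventional acceptable ranges are |d| <
#' 0.25 and variance ratio in [0.5, 2.0]; out-of-range values are flagged.
#'
#' @param covariates baseline covariate data.frame (factors are expanded to
#'   level indicators).
#' @param treatment 0/1 vector.
#' @param weights optional nonnegative weights (default 1).
#' @return object of class `balance_report`: per-covariate table and `asam`.
#' @export
balance_report <- function(covariates, treatment, weights = NULL) {
  X <- model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(X))
  res <- lapply(colnames(X), function(cn) {
    x <- X[, cn]
    i1 <- treatment == 1; i0 <- !i1
    m1 <- w_mean(x[i1], weights[i1]); m0 <- w_mean(x[i0], weights[i0])
    binary <- all(x %in% c(0, 1))
    if (binary) {
      v1 <- m1 * (1 - m1); v0 <- m0 * (1 - m0)
    } else {
      v1 <- w_var(x[i1], weights[i1]); v0 <- w_var(x[i0], weights[i0])
    }
    pooled <- sqrt((v1 + v0) / 2)
    d <- if (pooled > 0) (m1 - m0) / pooled else if (m1 == m0) 0 else Inf
    vr <- if (v0 > 0) v1 / v0 else NA_real_
    data.frame(covariate = cn, std_diff = d, variance_ratio = vr,
               flag = abs(d) >= 0.25 | (!is.na(vr) & (vr < 0.5 | vr > 2.0)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  structure(list(table = tab, asam = mean(abs(tab$std_diff))),
            class = "balance_report")
}

#' @method print balance_report
#' @export
print.balance_report <- function(x, ...) {
  cat("Covariate balance (ASAM =", round(x$asam, 4), ")\n")
  print(transform(x$table, std_diff = round(std_diff, 4),
                  variance_ratio = round(variance_ratio, 4)),
        row.names = FALSE)
  invisible(x)
}
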