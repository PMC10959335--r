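# Outcome-model strategies: survival regressions predicted on the functional
# scale (RMST or -log S(t0) given covariates and arm), and machine-learning
# regressions of the pseudo-outcome on covariates + arm.

# Breslow baseline cumulative hazard from linear predictors (exp scale lp),
# as a step function (times, hazard); used for penalised Cox where coxph's
# basehaz is unavailable.
breslow_basehaz <- function(time, event, risk) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]; r_s <- risk[o]
  te <- unique(t_s[e_s == 1])
  denom <- vapply(te, function(tk) sum(r_s[t_s >= tk]), numeric(1))
  d <- vapply(te, function(tk) sum(e_s == 1 & t_s == tk), numeric(1))
  data.frame(time = te, hazard = cumsum(d / denom))
}

# functional-scale predictions from a PH model: H0 step function + risk score
ph_functional <- function(bh, risk, functional, t0) {
  H0_t0 <- c(0, bh$hazard)[findInterval(t0, bh$time) + 1L]
  if (functional == "cumhaz") return(H0_t0 * risk)
  # RMST_i = sum_j S(t_j | x_i) * dt_j over the baseline step grid, chunked
  tt <- bh$time[bh$time <= t0]
  H0 <- bh$hazard[bh$time <= t0]
  dt <- diff(c(0, tt, t0))
  Hgrid <- c(0, H0)                          # S on [0,t1), [t1,t2), ...
  out <- numeric(length(risk))
  chunk <- 500L
  for (s in seq(1, length(risk), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(risk))
    out[idx] <- drop(exp(-outer(risk[idx], Hgrid)) %*% dt)
  }
  out
}

# fit the configured outcome model on a data.frame with .trt, time_years,
# event, pseudo (.y) and covariate columns; returns predict(covs, trt)
outcome_fitter <- function(spec, data, covnames, functional, t0) {
  hp <- spec$hyperparameters
  trt_int <- hp$trt_interactions %||% TRUE

  if (spec$outcome_model %in% c("random_forest", "gradient_boosting")) {
    # pseudo-outcome regression on covariates + arm
    df <- data.frame(.trt = data$.trt, data[, covnames, drop = FALSE],
                     check.names = TRUE)
    if (spec$outcome_model == "random_forest") {
      fit <- ranger::ranger(y = data$.y, x = df,
                            num.trees = hp$num_trees %||% 300,
                            min.node.size = hp$min_node_size %||% 20,
                            seed = sample.int(.Machine$integer.max, 1),
                            num.threads = 1)
      pred <- function(covs, trt) {
        nd <- data.frame(.trt = trt, covs, check.names = TRUE)
        predict(fit, data = nd, num.threads = 1)$predictions
      }
    } else {
      X <- model.matrix(~ ., df)[, -1, drop = FALSE]
      fit <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror",
                      max_depth = hp$max_depth %||% 3,
                      eta = hp$eta %||% 0.1, nthread = 1,
                      min_child_weight = hp$min_child_weight %||% 10,
                      seed = sample.int(.Machine$integer.max, 1)),
        data = xgboost::xgb.DMatrix(X, label = data$.y, nthread = 1),
        nrounds = hp$nrounds %||% 100, verbose = 0)
      cols <- colnames(X)
      pred <- function(covs, trt) {
        nd <- data.frame(.trt = trt, covs, check.names = TRUE)
        Xn <- model.matrix(~ ., nd)[, -1, drop = FALSE]
        predict(fit, xgboost::xgb.DMatrix(Xn[, cols, drop = FALSE],
                                          nthread = 1))
      }
    }
    if (functional %in% c("cumhaz", "binary"))
      return(function(covs, trt) pmax(pred(covs, trt), 0))
    return(pred)
  }

  # survival models; per-arm fits drop the treatment term
  fit_one <- function(d, with_trt) {
    rhs <- if (with_trt) c(".trt", covnames) else covnames
    if (spec$outcome_model == "cox_main_effects") {
      f <- reformulate(rhs, response = "survival::Surv(time_years, event)")
      fit <- survival::coxph(as.formula(f), data = d, ties = "efron",
                             x = FALSE, model = TRUE)
      bh <- survival::basehaz(fit, centered = FALSE)
      bh <- data.frame(time = bh$time, hazard = bh$hazard)
      list(risk = function(nd) predict(fit, newdata = nd, type = "risk",
                                       reference = "zero"),
           bh = bh)
    } else if (spec$outcome_model == "cox_two_way") {
      # two-way interactions among covariates, with or without
      # treatment-by-covariate terms
      f <- if (trt_int || !with_trt)
        as.formula(paste("survival::Surv(time_years, event) ~ (",
                         paste(rhs, collapse = " + "), ")^2"))
      else
        as.formula(paste("survival::Surv(time_years, event) ~ .trt + (",
                         paste(covnames, collapse = " + "), ")^2"))
      fit <- survival::coxph(f, data = d, ties = "efron", model = TRUE)
      bh <- survival::basehaz(fit, centered = FALSE)
      list(risk = function(nd) predict(fit, newdata = nd, type = "risk",
                                       reference = "zero"),
           bh = data.frame(time = bh$time, hazard = bh$hazard))
    } else if (spec$outcome_model == "parametric_survival") {
      f <- reformulate(rhs, response = "survival::Surv(time_years, event)")
      fit <- survival::survreg(as.formula(f), data = d, dist = "weibull")
      shape <- 1 / fit$scale
      list(weibull = TRUE, shape = shape,
           lp = function(nd) predict(fit, newdata = nd, type = "lp"))
    } else {                                  # penalised_cox
      f2 <- reformulate(rhs)
      X <- pad_design(model.matrix(f2, d)[, -1, drop = FALSE])
      y <- survival::Surv(d$time_years, d$event)
      fit <- glmnet::cv.glmnet(X, y, family = "cox",
                               alpha = hp$alpha %||% 0.5,
                               nfolds = hp$nfolds %||% 5)
      risk_tr <- drop(predict(fit, newx = X, s = "lambda.min",
                              type = "response"))
      bh <- breslow_basehaz(d$time_years, d$event, risk_tr)
      cols <- colnames(X)
      list(risk = function(nd) {
        Xn <- pad_design(model.matrix(f2, nd)[, -1, drop = FALSE])
        drop(predict(fit, newx = Xn[, cols, drop = FALSE], s = "lambda.min",
                     type = "response"))
      }, bh = bh)
    }
  }
  predict_one <- function(m, covs, trt) {
    nd <- data.frame(.trt = trt, covs, check.names = TRUE)
    if (isTRUE(m$weibull)) {
      lp <- m$lp(nd)
      if (functional == "cumhaz") return((t0 / exp(lp))^m$shape)
      grid <- seq(0, t0, length.out = 101)
      S <- exp(-outer((1 / exp(lp))^m$shape, grid^m$shape))
      h <- grid[2] - grid[1]
      w <- c(1, rep(c(4, 2), 49), 4, 1)
      drop(S %*% w) * h / 3                   # Simpson
    } else {
      ph_functional(m$bh, m$risk(nd), functional, t0)
    }
  }

  if (spec$per_arm) {
    m0 <- fit_one(data[data$.trt == 0, , drop = FALSE], with_trt = FALSE)
    m1 <- fit_one(data[data$.trt == 1, , drop = FALSE], with_trt = FALSE)
    function(covs, trt) {
      p0 <- predict_one(m0, covs, trt = rep(0, nrow(covs)))
      p1 <- predict_one(m1, covs, trt = rep(1, nrow(covs)))
      ifelse(trt == 1, p1, p0)
    }
  } else {
    m <- fit_one(data, with_trt = TRUE)
    function(covs, trt) predict_one(m, covs, trt)
  }
}

#' Direct outcome-regression ATE
#'
#' Fits the strategy's outcome model (Cox with main effects or all two-way
#' interactions, penalised Cox, parametric Weibull, or a machine-learning
#' regression of pseudo-outcomes on covariates and arm), produces
#' counterfactual predictions for every patient by toggling the arm, and
#' contrasts the counterfactual means on the estimand scale. Survival-model
#' predictions are converted to the functional scale (RMST by integrating the
#' fitted per-patient survival curve to `t0`; `-log S(t0)` as the fitted
#' cumulative hazard). `per_arm = TRUE` fits the model separately in each arm.
#'
#' @param spec a [strategy_spec()] with `outcome_model != "none"`.
#' @param data data.frame with columns `time_years`, `event`, the covariates
#'   and a 0/1 column named by `trt_col`.
#' @param pseudo pseudo-outcome vector (training response for the ML models).
#' @param covnames covariate column names.
#' @param functional,t0 estimand scale and cut-off.
#' @param trt_col name of the 0/1 treatment column.
#' @return a `strategy_fit`.
#' @export
outcome_regression_ate <- function(spec, data, pseudo, covnames, functional,
                                   t0, trt_col = ".trt") {
  d <- data
  d$.trt <- d[[trt_col]]
  d$.y <- pseudo
  pr <- outcome_fitter(spec, d, covnames, functional, t0)
  covs <- d[, covnames, drop = FALSE]
  m0 <- pr(covs, rep(0, nrow(d)))
  m1 <- pr(covs, rep(1, nrow(d)))
  strategy_fit(ate = estimand_from_means(mean(m0), mean(m1), functional),
               factual = ifelse(d$.trt == 1, m1, m0), m0 = m0, m1 = m1)
}
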