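engine_data <- function(n, seed = 1, effect = 0, conf = 0) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  trt <- rbinom(n, 1, plogis(conf * (z - 0.5)))
  lam <- 0.15 * exp(0.5 * z + effect * trt)
  tt <- rexp(n, lam); cc <- pmin(rexp(n, 0.03), 15)
  data.frame(.trt = trt, z = z, time_years = pmin(tt, cc),
             event = as.integer(tt <= cc))
}

test_that("leave-one-out arm means predict each patient's arm complement", {
  set.seed(10)
  d <- engine_data(30)
  y <- rnorm(30)
  p <- crossval_factual_predictions(strategy_spec("unadjusted"), d, y, "z",
                                    "rmst", 3.2, n_folds = 30)
  oracle <- vapply(seq_len(30), function(i) {
    same <- d$.trt == d$.trt[i]; same[i] <- FALSE
    mean(y[same])
  }, numeric(1))
  expect_equal(p, oracle, tolerance = 1e-12)
})

test_that("cross-validated predictions are reproducible under a seed", {
  d <- engine_data(120, seed = 3)
  y <- build_pseudo(d, arm_col = ".trt", functional = "cumhaz", t0 = 3.2)
  spec <- strategy_spec("s", "gradient_boosting", "ipw")
  set.seed(5); p1 <- crossval_factual_predictions(spec, d, y, "z", "cumhaz",
                                                  3.2, n_folds = 5)
  set.seed(5); p2 <- crossval_factual_predictions(spec, d, y, "z", "cumhaz",
                                                  3.2, n_folds = 5)
  expect_identical(p1, p2)
})

test_that("CvMSPE follows its formula", {
  expect_equal(cvmspe(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(cvmspe(c(1, 2, 3, 4), c(1, 2, 2, 5)), 0.5)
  # constant prediction at the pooled mean gives the pooled variance
  set.seed(2); y <- rnorm(50)
  expect_equal(cvmspe(y, rep(mean(y), 50)), mean((y - mean(y))^2))
  expect_error(cvmspe(1:3, 1:4), "aligned")
})

test_that("vectorized CvMSPE equals a per-patient loop", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    y <- rnorm(n); m <- rnorm(n)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (y[j] - m[j])^2
    expect_equal(cvmspe(y, m), acc / n, tolerance = 1e-12)
  }
})

test_that("support weights satisfy their contract", {
  w <- fma_weights(c(0.5, 0.5, 0.5), n = 100)
  expect_equal(w, rep(1 / 3, 3))
  expect_identical(fma_weights(2.4, n = 50), 1)
  sc <- c(1.0, 2.0, 1.5, 1.0)
  w <- fma_weights(sc, n = 100)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))
  expect_true(all(diff(w[order(sc)]) <= 1e-12))          # monotone
  expect_equal(w[1], w[4])                               # ties equal
  # direct evaluation of the softmax rule
  ref <- exp(-100 * (sc - 1) / (2 * 1)); ref <- ref / sum(ref)
  expect_equal(w, ref)
  expect_error(fma_weights(numeric(0), 10), "empty")
  expect_error(fma_weights(c(1, NA), 10), "finite")
  # alternative rules
  expect_equal(fma_weights(c(1, 2), 10, rule = "inverse"), c(2, 1) / 3)
  expect_equal(fma_weights(c(1, 2), 10, rule = "best"), c(1, 0))
})

test_that("model averaging respects weights and the log scale for ratios", {
  expect_equal(fma_estimate(c(0.8, 0.8, 0.8), rep(1 / 3, 3), "cumhaz"), 0.8)
  expect_equal(fma_estimate(c(0.6, 2.0), c(1, 0), "cumhaz"), 0.6)
  expect_equal(fma_estimate(c(0.5, 2.0), c(0.5, 0.5), "cumhaz"), 1.0)
  expect_equal(fma_estimate(c(1, 3), c(0.25, 0.75), "rmst"), 2.5)
})

test_that("CvMSPE is stable between 5- and 10-fold cross-validation", {
  d <- engine_data(500, seed = 8, effect = log(0.7), conf = 1)
  y <- build_pseudo(d, arm_col = ".trt", functional = "cumhaz", t0 = 3.2)
  spec <- strategy_spec("s", outcome_model = "cox_main_effects")
  set.seed(1)
  c5 <- cvmspe(y, crossval_factual_predictions(spec, d, y, "z", "cumhaz",
                                               3.2, n_folds = 5))
  set.seed(2)
  c10 <- cvmspe(y, crossval_factual_predictions(spec, d, y, "z", "cumhaz",
                                                3.2, n_folds = 10))
  expect_lt(abs(c5 - c10) / c10, 0.10)
})

test_that("the fitted object carries estimates, weights and metadata", {
  cfg <- confounded_config(51, 400)
  coh <- simulate_cohort(cfg)
  fit <- fma(fma_formula, coh, roster = reduced_roster(), n_folds = 5,
             n_bootstrap = 0, seed = 3)
  expect_s3_class(fit, "fma")
  expect_equal(fit$arms, c("ref", "trt"))
  expect_equal(fit$n0 + fit$n1, nrow(coh))
  ps <- fit$per_strategy
  expect_equal(sum(ps$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(ps$weight[order(ps$cvmspe)]) <= 1e-12))
  expect_equal(fit$best_model$strategy, ps$strategy[which.min(ps$cvmspe)])
  # FMA lies inside the strategy range (log scale for ratios)
  expect_gte(fit$fma_ate, min(ps$ate)); expect_lte(fit$fma_ate, max(ps$ate))
  expect_output(print(fit), "FMA estimate")
  expect_output(print(summary(fit)), "Per-strategy")
  expect_equal(unname(coef(fit)["best_model"]), fit$best_model$ate)
  # determinism: same seed, same result
  fit2 <- fma(fma_formula, coh, roster = reduced_roster(), n_folds = 5,
              n_bootstrap = 0, seed = 3)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$per_strategy, fit2$per_strategy)
  expect_error(fma(fma_formula, coh, arms = c("ref", "nope"),
                   roster = reduced_roster()), "nope")
})

test_that("degenerate constant-outcome bootstrap yields a zero-width CI", {
  d <- data.frame(arm = factor(rep(c("a", "b"), each = 20)),
                  sex = rbinom(40, 1, 0.5),
                  time_years = rep(1, 40), event = rep(1L, 40))
  fit <- suppressWarnings(
    fma(survival::Surv(time_years, event) ~ arm + sex, d,
        estimand = "rmst_diff", t0 = 2,
        roster = list(strategy_spec("unadjusted")),
        n_folds = 5, n_bootstrap = 50, seed = 4))
  expect_equal(fit$fma_ate, 0)
  expect_equal(fit$ci_lower, 0)
  expect_equal(fit$ci_upper, 0)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), c(0, 0))
})

test_that("bootstrap confidence intervals are seed-reproducible", {
  cfg <- null_config(61, 120)
  coh <- simulate_cohort(cfg)
  roster <- list(strategy_spec("unadjusted"),
                 strategy_spec("ipw", "logistic", "ipw"))
  f1 <- fma(fma_formula, coh, roster = roster, n_folds = 5,
            n_bootstrap = 40, seed = 7)
  f2 <- fma(fma_formula, coh, roster = roster, n_folds = 5,
            n_bootstrap = 40, seed = 7)
  expect_identical(f1$bootstrap, f2$bootstrap)
  expect_identical(c(f1$ci_lower, f1$ci_upper), c(f2$ci_lower, f2$ci_upper))
  expect_lte(f1$ci_lower, f1$ci_upper)
})

test_that("failed strategies are dropped and logged, not imputed", {
  cfg <- sim_config(n_per_arm = c(ref = 40, trt = 40),
                    covariates = list(x = list(type = "continuous",
                                               mean = 0, sd = 1)),
                    propensity = list(trt = c(x = 0.8)),
                    outcome = list(family = "exponential", rate = 0.1),
                    seed = 71)
  coh <- simulate_cohort(cfg)
  # a matching strategy with an impossible caliper fails; the rest survive
  roster <- list(strategy_spec("unadjusted"),
                 strategy_spec("bad_match", "logistic", "matching",
                               hyperparameters = list(caliper_sd = 1e-12)))
  fit <- fma(survival::Surv(time_years, event) ~ arm + x, coh,
             roster = roster, n_folds = 5, n_bootstrap = 0, seed = 2)
  expect_equal(nrow(fit$per_strategy), 1)
  expect_match(fit$failed, "bad_match")
  expect_equal(sum(fit$per_strategy$weight), 1)
})

test_that("binary estimand path returns an odds ratio on the restricted set", {
  cfg <- confounded_config(81, 600)
  coh <- simulate_cohort(cfg)
  fit <- fma(fma_formula, coh, estimand = "odds_ratio",
             roster = list(strategy_spec("unadjusted"),
                           strategy_spec("ipw", "logistic", "ipw")),
             n_folds = 5, n_bootstrap = 0, seed = 5)
  expect_gt(fit$fma_ate, 0)
  # oracle: unadjusted OR from the restricted sample
  keep <- (coh$event == 1 & coh$time_years <= 3.2) | coh$time_years >= 3.2
  d <- coh[keep, ]
  p1 <- mean(d$event[d$arm == "trt"] == 1 & d$time_years[d$arm == "trt"] <= 3.2)
  p0 <- mean(d$event[d$arm == "ref"] == 1 & d$time_years[d$arm == "ref"] <= 3.2)
  or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  unadj <- fit$per_strategy$ate[fit$per_strategy$strategy == "unadjusted"]
  expect_equal(unadj, or)
})

test_that("report_forest tabulates results and round-trips through JSON", {
  cfg <- null_config(91, 100)
  coh <- simulate_cohort(cfg)
  roster <- list(strategy_spec("unadjusted"))
  fit <- fma(fma_formula, coh, roster = roster, n_folds = 5,
             n_bootstrap = 10, seed = 6)
  tab <- report_forest(list(composite = fit))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$estimate, fit$fma_ate)
  expect_equal(tab$n0, fit$n0)
  prefix <- file.path(withr::local_tempdir(), "report")
  report_forest(list(composite = fit), file = prefix)
  reloaded <- jsonlite::read_json(paste0(prefix, ".json"),
                                  simplifyVector = TRUE)
  expect_equal(reloaded$composite$estimate, fit$fma_ate)
  expect_equal(reloaded$composite$per_strategy$cvmspe,
               fit$per_strategy$cvmspe)
  csv <- read.csv(paste0(prefix, ".csv"))
  expect_equal(csv$estimate, fit$fma_ate)
  expect_error(report_forest(list()), "length")
})

test_that("region imputation is applied inside the pipeline", {
  cfg <- null_config(95, 80)
  coh <- simulate_cohort(cfg)
  coh$region <- sample(c("South", "West", NA), nrow(coh), replace = TRUE,
                       prob = c(0.6, 0.3, 0.1))
  fit <- fma(survival::Surv(time_years, event) ~ arm + sex + region, coh,
             roster = list(strategy_spec("unadjusted"),
                           strategy_spec("ipw", "logistic", "ipw")),
             n_folds = 5, n_bootstrap = 0, seed = 8)
  expect_s3_class(fit, "fma")
  expect_equal(nrow(fit$per_strategy), 2)
})
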