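test_that("the logistic GEE agrees with ordinary logistic regression when clusters are singletons", {
  d <- simulate_outcome_data(n_schools = 300, cluster_size = 1, icc = 0,
                             arm_logodds = 0.5, seed = 2)
  g <- gee_logit(y ~ arm + imd_decile, d, "school_id")
  o <- glm(y ~ arm + imd_decile, binomial, d)
  expect_equal(unname(coef(g)), unname(coef(o)), tolerance = 1e-8)
  # robust SEs exist and are positive
  expect_true(all(diag(g$robust.vcov) > 0))
})

test_that("the GEE rejects degenerate inputs", {
  d <- simulate_outcome_data(20, 5, icc = 0, seed = 1)
  d$y <- 1
  expect_error(gee_logit(y ~ arm, d, "school_id"), "constant")
  d2 <- simulate_outcome_data(20, 5, icc = 0, seed = 1)
  d2$dup <- d2$arm
  expect_error(gee_logit(y ~ arm + dup, d2, "school_id"), "rank deficient")
})

test_that("the primary ITT fit reports odds ratios with robust intervals", {
  d <- simulate_outcome_data(40, 12, icc = 0.05, arm_logodds = -0.6, seed = 4)
  d$anxiety_disorder_12m <- d$y
  est <- fit_primary_binary(d, analysis_spec())
  expect_s3_class(est, "effect_estimate")
  expect_true(est$ci[1] <= est$estimate && est$estimate <= est$ci[2])
  expect_gt(est$estimate, 0)
  expect_lt(est$estimate, 1)  # protective simulated effect
  crude <- fit_primary_binary(d, analysis_spec(crude = TRUE))
  expect_lt(abs(log(crude$estimate) - log(est$estimate)), 0.5)
  dd <- d
  dd$anxiety_disorder_12m <- NA
  expect_error(fit_primary_binary(dd, analysis_spec()), "missing")
})

test_that("continuous outcomes recover a simulated mean difference and SMD", {
  set.seed(10)
  d <- simulate_outcome_data(60, 15, icc = 0.05, seed = 10)
  u <- rnorm(60, 0, 0.5)
  d$baseline_score <- rnorm(nrow(d), 20, 4)
  d$score_12m <- d$baseline_score * 0.5 + 2 * d$arm + u[d$school_id] +
    rnorm(nrow(d), 0, 3)
  spec <- analysis_spec("score_12m", type = "continuous",
                        baseline = "baseline_score")
  est <- fit_secondary_continuous(d, spec, include_icc = TRUE)
  expect_lt(abs(est$estimate - 2), 0.5)
  expect_lt(abs(est$smd - 0.5), 0.12)
  expect_gte(est$icc_crude, 0)
  # permuted arm gives a null estimate
  d2 <- d
  set.seed(11)
  perm <- sample(unique(d2$school_id))
  arm_by_school <- tapply(d2$arm, d2$school_id, max)
  d2$arm <- unname(arm_by_school[as.character(perm[d2$school_id])])
  est2 <- fit_secondary_continuous(d2, spec)
  expect_lt(abs(est2$estimate), 3 * est2$se + 0.5)
  # zero-variance outcome errors
  d3 <- d
  d3$score_12m <- 1
  expect_error(fit_secondary_continuous(d3, spec), "zero variance")
})

test_that("with no clustering the mixed model matches ordinary least squares", {
  set.seed(12)
  d <- simulate_outcome_data(50, 8, icc = 0, seed = 12)
  d$ycont <- 1.5 * d$arm + rnorm(nrow(d))
  spec <- analysis_spec("ycont", type = "continuous", crude = TRUE)
  est <- suppressMessages(fit_secondary_continuous(d, spec))
  ols <- lm(ycont ~ arm, d)
  expect_equal(est$estimate, unname(coef(ols)[["arm"]]), tolerance = 1e-4)
})

test_that("ICC estimators recover simulated intra-school correlation", {
  set.seed(13)
  J <- 100
  u <- rnorm(J, 0, sqrt(0.25))  # icc = 0.2 against residual variance 1
  d <- data.frame(school_id = rep(1:J, each = 10), arm = 0)
  d$w <- u[d$school_id] + rnorm(nrow(d))
  icc_model <- estimate_icc(d, "w", type = "continuous")
  icc_anova <- anova_icc(d$w, d$school_id)
  expect_lt(abs(icc_model - icc_anova), 0.05)
  expect_lt(abs(icc_anova - 0.2), 0.08)
  # no between-school variance
  d$flat <- rnorm(nrow(d))
  expect_lt(estimate_icc(d, "flat", type = "continuous"), 0.03)
  expect_error(estimate_icc(d[d$school_id == 1, ], "w"), "2 schools")
  # binary latent-scale ICC recovered from the generator
  db <- simulate_outcome_data(150, 20, icc = 0.10, seed = 14)
  db$anxiety_disorder_12m <- db$y
  icc_b <- estimate_icc(db, "anxiety_disorder_12m", type = "binary")
  expect_lt(abs(icc_b - 0.10), 0.06)
})

test_that("Rubin pooling follows the closed-form arithmetic", {
  p0 <- pool_rubin(c(1, 1), c(0.5, 0.5))
  expect_equal(p0$estimate, 1)
  expect_equal(p0$se, 0.5)
  expect_equal(p0$between, 0)
  p <- pool_rubin(c(0, 2), c(1, 1))
  expect_equal(p$pooled_q, 1)
  expect_equal(p$between, 2)
  expect_equal(p$total, 1 + 1.5 * 2)
  expect_equal(p$se, 2)
  expect_true(p$ci[1] < 1 && p$ci[2] > 1)
  p50a <- pool_rubin(rep(c(0.4, 0.6), 25), rep(0.2, 50))
  p50b <- pool_rubin(rep(c(0.4, 0.6), 25), rep(0.2, 50))
  expect_identical(p50a, p50b)
  expect_error(pool_rubin(c(1, 2), 1), "equal length")
  expect_error(pool_rubin(1, 1), "at least 2")
  # OR pooling happens on the log scale
  plog <- pool_rubin(log(c(0.8, 1.25)), c(0.1, 0.1), log = TRUE)
  expect_equal(plog$estimate, 1, tolerance = 1e-12)
})

test_that("moderation tests control size under homogeneity and detect opposite effects", {
  rej <- vapply(1:100, function(s) {
    d <- simulate_outcome_data(40, 10, icc = 0.05, arm_logodds = -0.5,
                               seed = s)
    d$anxiety_disorder_12m <- d$y
    res <- test_moderation(d, "gender",
                           analysis_spec(adjust = c("fsm_stratum",
                                                    "imd_decile")))
    res$interaction_p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.12)
  expect_gte(mean(rej), 0.005)
  # strong opposite effects by gender are detected
  det <- vapply(1:20, function(s) {
    d <- simulate_outcome_data(60, 15, icc = 0.05, seed = 100 + s)
    sex <- d$gender == "female"
    eta <- ifelse(sex, 1, -1) * d$arm + d$outcome_latent -
      (d$y * 0)  # latent includes u + logistic noise, no arm effect
    d$anxiety_disorder_12m <- as.integer(eta > 0)
    res <- test_moderation(d, "gender",
                           analysis_spec(adjust = c("fsm_stratum",
                                                    "imd_decile")))
    res$interaction_p < 0.05
  }, TRUE)
  expect_gte(mean(det), 0.8)
  d1 <- simulate_outcome_data(20, 10, seed = 3)
  d1$anxiety_disorder_12m <- d1$y
  d1$mod1 <- "only"
  expect_error(test_moderation(d1, "mod1", analysis_spec(adjust = NULL)),
               "fewer than 2")
})

test_that("the within-window sensitivity filter keeps +12 weeks only", {
  d <- data.frame(fu_weeks_late = c(11, 12, 13, NA), id = 1:4)
  kept <- sensitivity_within_window(d)
  expect_equal(kept$id, c(1, 2))
  expect_equal(nrow(sensitivity_within_window(d[0, ])), 0)
  expect_error(sensitivity_within_window(data.frame(id = 1)), "not found")
})
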