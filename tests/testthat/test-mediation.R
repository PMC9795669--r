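med_covs <- c("fsm_stratum", "imd_decile")

test_that("indirect effect and proportion mediated follow the product-of-paths arithmetic", {
  a <- rep(0.5, 100)
  b <- rep(0.4, 100)
  cp <- rep(0.3, 100)
  ie <- indirect_effect(a, b, cp)
  expect_equal(unique(ie$ab), 0.2)
  expect_equal(ie$summary$ab_mean, 0.2)
  expect_equal(ie$summary$prop_mean, 0.2 / 0.5)
  expect_true(ie$summary$ab_cri[1] <= ie$summary$ab_cri[2])
  expect_error(indirect_effect(a, b[1:50], cp), "equal length")
  expect_error(indirect_effect(c(a, NA), c(b, 1), c(cp, 1)), "non-finite")
  # symmetric-about-zero b gives an ab posterior centred at ~0
  set.seed(1)
  b0 <- rnorm(4000, 0, 0.3)
  a1 <- rnorm(4000, 0.5, 0.1)
  ie0 <- suppressWarnings(indirect_effect(a1, b0, rnorm(4000, 0.3, 0.1)))
  expect_lt(abs(ie0$summary$ab_mean), 0.02)
  expect_true(ie0$summary$ab_cri[1] < 0 && ie0$summary$ab_cri[2] > 0)
})

test_that("pooling across imputations concatenates draws", {
  set.seed(2)
  d1 <- indirect_effect(rnorm(500, 0.5, 0.05), rnorm(500, 0.4, 0.05),
                        rnorm(500, 0.3, 0.05))
  pooled_same <- pool_across_imputations(list(d1, d1))
  expect_equal(pooled_same$summary$ab_mean, d1$summary$ab_mean)
  # percentiles of the duplicated draw set differ only by interpolation
  expect_equal(pooled_same$summary$ab_cri, d1$summary$ab_cri,
               tolerance = 0.02)
  expect_length(pooled_same$ab, 2 * length(d1$ab))
  d2 <- indirect_effect(rnorm(500, 0.1, 0.05), rnorm(500, 0.1, 0.05),
                        rnorm(500, 0.3, 0.05))
  pooled <- pool_across_imputations(list(d1, d2, d2))
  expect_length(pooled$ab, 1500)
  expect_error(pool_across_imputations(list()), "no draw sets")
})

test_that("the mediator model recovers a simulated arm-to-mediator path", {
  d <- simulate_outcome_data(60, 10, icc = 0.05, mediator_a = 0.5,
                             mediator_b = 0.4, seed = 3)
  spec <- mediation_spec("mediator", covariates = med_covs, chains = 2,
                         iter = 600, warmup = 400, seed = 1)
  med <- suppressWarnings(sample_mediator_model(d, spec))
  expect_lt(abs(mean(med$a) - 0.5), 0.25)
  expect_true(is.finite(med$diag$rhat))
  expect_match(med$priors, "normal")
  # school-permuted arm concentrates a near zero
  d2 <- d
  set.seed(4)
  arm_by_school <- tapply(d2$arm, d2$school_id, max)
  d2$arm <- unname(sample(arm_by_school)[d2$school_id])
  med2 <- suppressWarnings(sample_mediator_model(d2, spec))
  expect_lt(abs(mean(med2$a)), 0.25)
})

test_that("the outcome model recovers mediator and direct paths", {
  d <- simulate_outcome_data(60, 12, icc = 0.05, mediator_a = 0.5,
                             mediator_b = 0.4, seed = 5)
  d$anxiety_disorder_12m <- d$y
  spec <- mediation_spec("mediator", covariates = med_covs, chains = 2,
                         iter = 600, warmup = 400, seed = 2)
  out <- suppressWarnings(sample_outcome_model(d, spec))
  expect_lt(abs(mean(out$b) - 0.4), 0.2)
  expect_lt(abs(mean(out$c_prime)), 0.45)  # simulated direct effect is zero
  tot <- suppressWarnings(sample_total_model(d, spec))
  # total effect of arm operates only through the mediator: c approx a*b
  expect_lt(abs(mean(tot$c)) , 0.6)
  expect_equal(length(tot$c), 2 * 600)
})

test_that("posterior means match maximum-likelihood oracles under flat-ish priors", {
  # one cluster, individually randomised arm: the samplers drop the school
  # random intercept and the ML fits are the exact frequentist analogue
  set.seed(9)
  n <- 400
  d <- data.frame(school_id = 1, arm = rbinom(n, 1, 0.5))
  d$mediator <- 0.5 * d$arm + rnorm(n)
  d$y <- rbinom(n, 1, plogis(0.5 * d$mediator))
  spec <- mediation_spec("mediator", covariates = character(0),
                         prior_scale = 50, chains = 2, iter = 1000,
                         warmup = 500, seed = 3)
  med <- suppressWarnings(sample_mediator_model(d, spec))
  a_ml <- coef(lm(mediator ~ arm, d))[["arm"]]
  expect_lt(abs(mean(med$a) - a_ml) / abs(a_ml), 0.05)
  out <- suppressWarnings(sample_outcome_model(d, spec, outcome = "y"))
  b_ml <- coef(glm(y ~ arm + mediator, binomial, d))[["mediator"]]
  expect_lt(abs(mean(out$b) - b_ml) / abs(b_ml), 0.05)
})

test_that("the posterior is dominated by the likelihood at large n", {
  d <- simulate_outcome_data(40, 25, icc = 0.02, mediator_a = 0.5, seed = 11)
  base <- mediation_spec("mediator", covariates = character(0), chains = 2,
                         iter = 500, warmup = 300, seed = 4)
  wide <- base
  wide$prior_scale <- 250
  m1 <- suppressWarnings(sample_mediator_model(d, base))
  m2 <- suppressWarnings(sample_mediator_model(d, wide))
  expect_lt(abs(mean(m1$a) - mean(m2$a)), 0.05)
})

test_that("mediate() pools per-imputation posteriors and reports diagnostics", {
  sets <- lapply(1:2, function(s) {
    d <- simulate_outcome_data(40, 10, icc = 0.05, mediator_a = 0.5,
                               mediator_b = 0.5, seed = 20 + s)
    d$anxiety_disorder_12m <- d$y
    d
  })
  spec <- mediation_spec("mediator", covariates = med_covs, chains = 2,
                         iter = 400, warmup = 300, seed = 6)
  pooled <- suppressWarnings(mediate(sets, spec))
  per <- attr(pooled, "per_imputation")
  expect_length(per, 2)
  expect_length(pooled$ab, sum(vapply(per, function(p) length(p$ab), 1)))
  expect_gt(pooled$summary$ab_mean, 0)
})
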