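test_that("binary rounding and categorical reconstruction follow the stated rules", {
  expect_identical(round_binary(c(0.49, 0.5, -0.2, 1.7)), c(0L, 1L, 0L, 1L))
  expect_error(round_binary(NaN), "non-finite")
  # k = 3: reference value 1 - (0.2 + 0.3) = 0.5 is the largest -> level 3
  expect_equal(assign_categorical(c(0.2, 0.3)), 3)
  expect_equal(assign_categorical(0.9), 1)
  # exact tie: lowest level index wins
  expect_equal(assign_categorical(0.5), 1)
  expect_error(assign_categorical(numeric(0)), "empty")
})

make_mcar_data <- function(seed, n = 300, J = 20, miss = 0.3) {
  set.seed(seed)
  u <- rnorm(J, 0, 0.5)
  sch <- rep(seq_len(J), each = n / J)
  x <- rnorm(n, 5, 2) + u[sch]
  y <- 0.5 * x + rnorm(n) + u[sch]
  d <- data.frame(school_id = sch, x = x, y = y)
  dm <- d
  dm$x[runif(n) < miss] <- NA
  dm$y[runif(n) < miss] <- NA
  list(full = d, miss = dm)
}

test_that("a complete table yields identical imputed datasets equal to the input", {
  dd <- make_mcar_data(1)$full
  spec <- imputation_spec(c("x", "y"), m = 3, burnin = 30, thin = 5, seed = 2)
  imp <- draw_imputations(fit_joint_model(dd, spec))
  expect_identical(imp$datasets[[1]], dd)
  expect_identical(imp$datasets[[1]], imp$datasets[[3]])
  # between-imputation variance of a complete variable is exactly 0
  expect_equal(var(vapply(imp$datasets, function(d) mean(d$x), 1)), 0)
})

test_that("draws are seed-deterministic and preserve observed cells bitwise", {
  dd <- make_mcar_data(2)$miss
  spec <- imputation_spec(c("x", "y"), m = 4, burnin = 100, thin = 10,
                          seed = 7)
  st <- fit_joint_model(dd, spec)
  imp1 <- draw_imputations(st)
  imp2 <- draw_imputations(st)
  expect_identical(serialize(imp1$datasets, NULL),
                   serialize(imp2$datasets, NULL))
  obs <- !is.na(dd$x)
  for (d in imp1$datasets) {
    expect_identical(d$x[obs], dd$x[obs])
    expect_false(any(is.na(d$x)))
  }
})

test_that("MCAR deletion leaves Rubin-pooled means unbiased with T >= W", {
  dat <- make_mcar_data(3)
  spec <- imputation_spec(c("x", "y"), m = 10, burnin = 200, thin = 20,
                          seed = 5)
  imp <- draw_imputations(fit_joint_model(dat$miss, spec))
  est <- vapply(imp$datasets, function(d) mean(d$x), 1)
  ses <- vapply(imp$datasets, function(d) sd(d$x) / sqrt(nrow(d)), 1)
  pooled <- pool_rubin(est, ses)
  # full-data mean x has SE ~ 0.12; allow calibration + MC slack
  expect_lt(abs(pooled$estimate - mean(dat$full$x)), 0.35)
  expect_gte(pooled$total, pooled$within)
  # total variance exceeds the complete-data sampling variance
  expect_gte(pooled$se, sd(dat$full$x) / sqrt(nrow(dat$full)) * 0.8)
})

test_that("the sampler recovers a simulated between-school variance component", {
  set.seed(6)
  J <- 100
  u <- rnorm(J, 0, sqrt(0.25))  # icc 0.2 with unit residual variance
  sch <- rep(seq_len(J), each = 8)
  w <- u[sch] + rnorm(length(sch))
  w[runif(length(sch)) < 0.2] <- NA
  d <- data.frame(school_id = sch, w = w, z = rnorm(length(sch)))
  spec <- imputation_spec(c("w", "z"), m = 10, burnin = 300, thin = 20,
                          seed = 8)
  imp <- draw_imputations(fit_joint_model(d, spec))
  psi_w <- mean(imp$psi_draws[, "w"])
  sig_w <- mean(imp$sigma_draws[, "w"])
  expect_lt(abs(psi_w - 0.25), 0.15)
  expect_lt(abs(psi_w / (psi_w + sig_w) - 0.2), 0.08)
})

test_that("binary, categorical and transformed variables impute on the right scales", {
  set.seed(9)
  n <- 400
  sch <- rep(1:20, each = n / 20)
  lat <- rnorm(n)
  d <- data.frame(
    school_id = sch,
    ybin = as.integer(lat + rnorm(n) > 0),
    grp = sample(c("a", "b", "c"), n, replace = TRUE),
    pos = exp(rnorm(n, 1, 0.4)),
    z = lat
  )
  d$ybin[runif(n) < 0.3] <- NA
  d$grp[runif(n) < 0.3] <- NA
  d$pos[runif(n) < 0.3] <- NA
  spec <- imputation_spec(c("ybin", "grp", "pos", "z"), binary = "ybin",
                          categorical = list(grp = c("a", "b", "c")),
                          transform = c(pos = "log"),
                          m = 3, burnin = 100, thin = 10, seed = 3)
  imp <- draw_imputations(fit_joint_model(d, spec))
  for (dd in imp$datasets) {
    expect_true(all(dd$ybin %in% 0:1))
    expect_true(all(dd$grp %in% c("a", "b", "c")))
    expect_true(all(dd$pos > 0))  # log-scale imputation back-transforms
  }
})

test_that("the model spec enforces its preconditions", {
  d <- make_mcar_data(4)$miss
  expect_error(imputation_spec("x", m = 1), "m must be >= 2")
  bad <- d
  bad$x <- NA_real_
  spec <- imputation_spec(c("x", "y"), m = 2, burnin = 10, thin = 2)
  expect_error(fit_joint_model(bad, spec), "no observed values")
  one <- d[d$school_id == 1, ]
  expect_error(fit_joint_model(one, spec), "2 schools")
  # control-arm auxiliary must be zero
  d$arm <- rep(c(0, 1), length.out = nrow(d))
  d$modules_completed <- 3
  spec2 <- imputation_spec(c("x", "y", "modules_completed"), m = 2,
                           burnin = 10, thin = 2)
  expect_error(fit_joint_model(d, spec2), "zero in the control arm")
})
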