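test_that("generation is a pure function of (config, seed)", {
  t1 <- small_cohort(11)
  t2 <- small_cohort(11)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  t3 <- small_cohort(12)
  expect_false(identical(t1$master, t3$master))
})

test_that("a zero participation rate empties the funnel", {
  tt <- generate_cohort(sim_config(n_schools = 6, participation_rate = 0,
                                   seed = 1))
  fc <- funnel_counts(tt)
  expect_gt(fc$overall[fc$stage == "invited"], 0)
  expect_equal(fc$overall[fc$stage == "screened"], 0)
  expect_equal(fc$overall[fc$stage == "enrolled"], 0)
})

test_that("config validation rejects out-of-range values", {
  expect_error(sim_config(participation_rate = 1.2), "\\[0,1\\]")
  expect_error(sim_config(icc_latent = 1), "\\[0,1\\)")
  expect_error(sim_config(baseline_logit = Inf), "finite")
})

test_that("funnel counts are monotone and structural invariants hold", {
  for (seed in 1:3) {
    tt <- default_cohort(seed)
    fc <- funnel_counts(tt)
    expect_true(all(diff(fc$overall) <= 0))
    expect_true(all(diff(fc$control[4:5]) <= 0))
    expect_true(all(diff(fc$intervention[4:5]) <= 0))
    m <- tt$master
    # control-arm children have no module completions
    expect_true(all(m$modules_completed[m$enrolled & m$arm == 0] == 0))
    # every enrolled child screens positive on >= 1 instrument
    enr <- m[m$enrolled, ]
    expect_true(all(enr$risk_child_anxiety | enr$risk_behavioural_inhibition |
                      enr$risk_parent_anxiety))
    # at most one enrolled child per household
    expect_lte(max(table(m$household_id[m$enrolled])), 1)
    # enrolled children all have an arm; non-enrolled none
    expect_true(all(!is.na(m$arm[m$enrolled])))
    expect_true(all(is.na(m$arm[!m$enrolled])))
  }
})

test_that("the default funnel matches the reviewed recruitment rates", {
  # replicate-averaged enrolment close to the 611 projection, screening
  # participation close to 17%, and enrolled cluster-size CV near 0.68
  reps <- 20
  stats <- sapply(seq_len(reps), function(s) {
    tt <- default_cohort(s)
    fc <- funnel_counts(tt)
    m <- tt$master
    sz <- as.numeric(table(factor(m$school_id,
                                  levels = unique(m$school_id))[m$enrolled]))
    c(enrolled = fc$overall[fc$stage == "enrolled"],
      part = fc$overall[2] / fc$overall[1],
      cv = sd(sz) / mean(sz))
  })
  # one replicate has SD ~ 80 enrolled; 3 x SE over 20 replicates ~ 55
  expect_lt(abs(mean(stats["enrolled", ]) - 611), 60)
  expect_lt(abs(mean(stats["part", ]) - 0.17), 0.015)
  expect_lt(abs(mean(stats["cv", ]) - 0.68), 0.1)
})

test_that("the latent-scale outcome ICC matches the configured value", {
  # effect-free clusters so the latent linear predictor is u_school + logistic
  iccs <- vapply(1:40, function(s) {
    d <- simulate_outcome_data(n_schools = 100, cluster_size = 30,
                               icc = 0.05, seed = s)
    anova_icc(d$outcome_latent, d$school_id)
  }, 1)
  expect_lt(abs(mean(iccs) - 0.05), 0.01)
})

test_that("a null configuration embeds independence of arm and outcome", {
  rej <- vapply(1:200, function(s) {
    d <- simulate_outcome_data(n_schools = 40, cluster_size = 10, icc = 0,
                               seed = s)
    suppressWarnings(stats::chisq.test(table(d$arm, d$y))$p.value) < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.10)
})

test_that("MAR missingness hits the configured rates and respects structure", {
  cfg <- sim_config(seed = 21)
  tt <- default_cohort(21)
  # zero rates leave the table unchanged
  cfg0 <- cfg
  cfg0$missingness <- list(measure_rates = c(t1 = 0, t2 = 0, t3 = 0),
                           item_rate = 0, arm_coef = 0, baseline_coef = 0)
  expect_identical(impose_missingness(tt, cfg0)$items, tt$items)
  # measure-level 20% at 12 months, default arm/baseline dependence
  cfg2 <- cfg
  cfg2$missingness <- list(measure_rates = c(t3 = 0.2), item_rate = 0,
                           arm_coef = 0.3, baseline_coef = 0.3)
  mt <- impose_missingness(tt, cfg2)
  pas_cols <- grep("^pas_i", names(mt$items$t3))
  miss_frac <- mean(rowSums(is.na(mt$items$t3[, pas_cols])) == 28)
  n3 <- nrow(mt$items$t3)
  expect_lt(abs(miss_frac - 0.2), 0.02 + 3 * sqrt(0.2 * 0.8 / n3))
  # latent fields never blanked
  expect_identical(mt$master$mediator_latent, tt$master$mediator_latent)
  # item-level gaps cascade into missing totals when >= 8 PAS items blank
  cfg3 <- cfg
  cfg3$missingness <- list(measure_rates = c(t2 = 0), item_rate = 0.35,
                           arm_coef = 0, baseline_coef = 0)
  mt3 <- impose_missingness(tt, cfg3)
  pas2 <- as.matrix(mt3$items$t2[, grep("^pas_i", names(mt3$items$t2))])
  totals <- score_measure(pas2, "pas")$total
  heavy <- rowSums(is.na(pas2)) >= 8
  expect_true(any(heavy))
  expect_true(all(is.na(totals[heavy])))
  expect_true(all(!is.na(totals[rowSums(is.na(pas2)) < 8])))
  expect_error({
    cfgbad <- cfg
    cfgbad$missingness$measure_rates <- c(t3 = 1.5)
    impose_missingness(tt, cfgbad)
  }, "\\[0,1\\]")
})

test_that("trial tables round-trip through delimited text", {
  tt <- small_cohort(31)
  dir <- tempfile("trial")
  write_trial_table(tt, dir)
  expect_true(file.exists(file.path(dir, "master.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_trial_table(dir)
  expect_equal(nrow(back$master), nrow(tt$master))
  expect_equal(back$master$child_id, tt$master$child_id)
  expect_equal(back$master$anxiety_disorder_12m, tt$master$anxiety_disorder_12m)
  expect_equal(names(back$items), names(tt$items))
  expect_equal(as.matrix(back$items$t2[, -1]), as.matrix(tt$items$t2[, -1]))
  expect_equal(back$config$seed, tt$config$seed)
  expect_equal(back$config$screen_positive_rate, tt$config$screen_positive_rate)
})

test_that("analysis_data assembles enrolled children with scored totals", {
  tt <- small_cohort(41)
  ad <- analysis_data(tt)
  expect_equal(nrow(ad), sum(tt$master$enrolled))
  expect_true(all(c("pas_t0", "pas_t2", "complier", "cluster_size") %in%
                    names(ad)))
  expect_true(all(ad$complier[ad$arm == 0] == 0))
  expect_true(all(ad$complier[ad$modules_completed >= 5 & ad$arm == 1] == 1))
})
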