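# Shared fixtures: cohorts are cached so several test files can reuse the
# same replicates without regenerating them.

.fixture_env <- new.env()

default_cohort <- function(seed) {
  key <- paste0("cohort", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}

small_cohort <- function(seed, ...) {
  generate_cohort(sim_config(n_schools = 12, seed = seed, ...))
}

# A tiny hand-built trial table with known counts: 10 invited, 4 screened,
# 3 screen positive, 2 enrolled (one control school, one intervention
# school), 1 followed up.
toy_table <- function() {
  master <- data.frame(
    child_id = 1:10,
    school_id = rep(1:2, each = 5),
    class_id = "c1", year_group = 1, batch = 1,
    fsm_pct = 10, fsm_stratum = "below",
    gender = rep(c("female", "male"), 5),
    imd_decile = 5,
    household_id = 1:10,
    screened = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
    pas_screen = c(40, 35, 10, 33, rep(NA, 6)),
    stsc_screen = c(10, 12, 31, 8, rep(NA, 6)),
    gad7_screen = c(2, 3, 1, 7, rep(NA, 6)),
    screen_positive = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 6)),
    risk_child_anxiety = c(TRUE, TRUE, FALSE, FALSE, rep(NA, 6)),
    risk_behavioural_inhibition = c(FALSE, FALSE, TRUE, FALSE, rep(NA, 6)),
    risk_parent_anxiety = c(FALSE, FALSE, FALSE, FALSE, rep(NA, 6)),
    household_selected = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 6)),
    enrolled = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6)),
    arm = c(0, 1, NA, NA, rep(NA, 6)),
    cluster_size = c(rep(1, 5), rep(1, 5)),
    complier_stratum = c(1, 1, NA, NA, rep(NA, 6)),
    modules_completed = c(0, 6, NA, NA, rep(NA, 6)),
    mediator_latent = c(0.2, -0.1, NA, NA, rep(NA, 6)),
    outcome_latent = c(0.5, -0.5, NA, NA, rep(NA, 6)),
    anxiety_disorder_12m = c(1, NA, NA, NA, rep(NA, 6)),
    followed_up_12m = c(TRUE, FALSE, NA, NA, rep(NA, 6)),
    fu_weeks_late = c(2, NA, NA, NA, rep(NA, 6))
  )
  pas0 <- matrix(1, 2, 28, dimnames = list(NULL, paste0("pas_i", 1:28)))
  t0 <- data.frame(child_id = c(1, 2), pas0)
  t3 <- data.frame(child_id = 1, matrix(2, 1, 28,
                                        dimnames = list(NULL,
                                                        paste0("pas_i", 1:28))))
  structure(list(master = master,
                 items = list(screening = data.frame(child_id = 1:4),
                              t0 = t0, t3 = t3),
                 schools = data.frame(school_id = 1:2, batch = 1,
                                      fsm_stratum = "below",
                                      recruited_pupils = 1, arm = 0:1),
                 config = sim_config()),
            class = "trial_table")
}

# Brute-force scoring oracle: reverse the listed items, then sum; prorate by
# mean * n_items. Independent of the package's scoring path.
oracle_total <- function(responses, spec) {
  r <- responses
  for (i in spec$reverse_items) r[i] <- spec$item_min + spec$item_max - r[i]
  if (isTRUE(spec$first_item_only)) return(r[1])
  sum(r)
}
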