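# Synthetic trial generator: schools, classes, screening funnel, latent-trait
# item responses, principal-stratum compliance, clustered binary outcome and
# continuous mediator. Stands in for the not-yet-collected trial data so the
# full analysis pipeline is testable.

# Base category probabilities on the *scored* scale for each instrument's
# items, frozen at package build. Item responses are generated from a
# per-child latent trait through ordinal probit thresholds; a common location
# shift is calibrated numerically so the enrolment rate among screened
# children matches the configured target (see `calibrate_screen_shift`).
.item_base_probs <- list(
  pas      = c(0.40, 0.30, 0.17, 0.09, 0.04),
  stsc_a   = c(0.28, 0.24, 0.18, 0.13, 0.10, 0.07),
  gad7     = c(0.55, 0.25, 0.13, 0.07),
  calis_pv = c(0.45, 0.27, 0.15, 0.08, 0.05),
  sdq_e    = c(0.55, 0.30, 0.15),
  pos      = c(0.35, 0.28, 0.18, 0.12, 0.07),
  psoc_se  = c(0.05, 0.10, 0.20, 0.30, 0.22, 0.13),
  camp     = c(0.50, 0.27, 0.15, 0.08),
  rules    = c(0.35, 0.27, 0.19, 0.12, 0.07),
  cq_p     = c(0.08, 0.12, 0.18, 0.24, 0.18, 0.12, 0.08),
  motivation = c(0.08, 0.15, 0.27, 0.30, 0.20)
)

# Instruments measured at each timepoint (the trial's data-collection
# schedule). Screening items are generated separately for screened children.
.schedule <- list(
  t0 = c("pas", "stsc_a", "gad7", "calis_pv", "sdq_e", "pos", "psoc_se",
         "rules", "cq_p", "camp", "motivation"),
  t1 = c("pas", "stsc_a", "gad7", "pos", "psoc_se", "rules", "cq_p", "camp"),
  t2 = c("pas", "stsc_a", "gad7", "calis_pv", "sdq_e", "pos", "psoc_se",
         "rules", "cq_p", "camp"),
  t3 = c("pas", "stsc_a", "gad7", "calis_pv", "sdq_e", "pos", "psoc_se",
         "rules", "cq_p", "camp")
)

# Ordinal thresholds on the latent scale z = theta + e, z ~ N(shift, 2).
item_thresholds <- function(inst) {
  probs <- .item_base_probs[[inst]]
  stats::qnorm(cumsum(probs)[-length(probs)]) * sqrt(2)
}

# Generate an n x n_items matrix of *scored-scale* item values from latent
# traits. Raw stored responses un-reverse the reverse-scored items so that
# score_measure() recovers the scored scale.
gen_items <- function(theta, inst, shift = 0, raw = TRUE) {
  spec <- instrument_spec(inst)
  n <- length(theta)
  k <- spec$n_items
  tau <- item_thresholds(inst)
  z <- theta + shift + matrix(stats::rnorm(n * k), n, k)
  scored <- matrix(spec$item_min + findInterval(as.vector(z), tau), n, k)
  if (raw && length(spec$reverse_items)) {
    ri <- spec$reverse_items
    scored[, ri] <- spec$item_min + spec$item_max - scored[, ri]
  }
  colnames(scored) <- paste0(inst, "_i", seq_len(k))
  scored
}

# Totals on the scored scale directly from traits (used by the calibration,
# which does not need raw item storage).
gen_totals <- function(theta, inst, shift, noise) {
  spec <- instrument_spec(inst)
  tau <- item_thresholds(inst)
  z <- theta + shift + noise
  rowSums(matrix(spec$item_min + findInterval(as.vector(z), tau),
                 nrow(noise), ncol(noise)))
}

.calib_env <- new.env(parent = emptyenv())

# Numerically calibrate the common latent shift applied to the three
# screening instruments so that the expected enrolled/screened fraction
# (net of household deduplication and enrolment decline) matches `target`.
# Monte-Carlo with common random numbers under a fixed internal seed; the
# result is cached per parameter combination.
calibrate_screen_shift <- function(target, trait_cor, household_cor,
                                   sibling_rate, decline_rate,
                                   n_mc = 100000) {
  key <- paste(round(c(target, trait_cor, household_cor, sibling_rate,
                       decline_rate), 6), collapse = "|")
  hit <- .calib_env[[key]]
  if (!is.null(hit)) return(hit)
  insts <- c("pas", "stsc_a", "gad7")
  shift <- with_seed(104729, {
    n_pairs <- floor(n_mc * sibling_rate / 2)
    hh <- c(rep(seq_len(n_pairs), each = 2),
            n_pairs + seq_len(n_mc - 2 * n_pairs))
    H <- stats::rnorm(max(hh))[hh]
    C <- sqrt(household_cor) * H + sqrt(1 - household_cor) * stats::rnorm(n_mc)
    theta <- lapply(insts, function(i) {
      sqrt(trait_cor) * C + sqrt(1 - trait_cor) * stats::rnorm(n_mc)
    })
    names(theta) <- insts
    noise <- lapply(insts, function(i) {
      k <- instrument_spec(i)$n_items
      matrix(stats::rnorm(n_mc * k), n_mc, k)
    })
    names(noise) <- insts
    cutoffs <- vapply(insts, function(i) instrument_spec(i)$screen_cutoff, 1)
    g <- function(s) {
      pos <- rep(FALSE, n_mc)
      for (i in insts) {
        tot <- gen_totals(theta[[i]], i, s, noise[[i]])
        pos <- pos | (tot >= cutoffs[[i]])
      }
      # at most one enrolled child per household
      n_sel <- sum(tapply(pos, hh, any))
      n_sel * (1 - decline_rate) / n_mc - target
    }
    lo <- g(-2.5); hi <- g(2.5)
    if (lo > 0 || hi < 0) stop("screen-positive target outside calibratable range",
                               call. = FALSE)
    stats::uniroot(g, c(-2.5, 2.5), tol = 1e-3)$root
  })
  .calib_env[[key]] <- shift
  shift
}

#' Simulation configuration for the synthetic trial generator
#'
#' Defaults encode the reviewed recruitment assumptions and analysis model:
#' 60 schools, two sampled classes in each of three year groups, a mean of 27
#' pupils per class, 17% screening participation, 37% of screened children
#' enrolling, 80% twelve-month follow-up, latent-scale outcome ICC 0.05 and
#' an enrolled cluster-size coefficient of variation of 0.68 (induced by
#' gamma-distributed school-level participation heterogeneity). The default
#' intervention effect acts only through compliance (complier log-odds
#' `-1.05` with complier probability 0.6, approximating the 0.50 vs 0.35
#' design alternative marginally); direct (`c_prime`) and mediated (`a`, `b`)
#' paths default to zero and can be switched on for mediation studies.
#'
#' @param n_schools Number of schools.
#' @param classes_per_year Classes available per year group (3 year groups;
#'   two are sampled per year group).
#' @param pupils_per_class_mean Mean pupils per sampled class (Poisson).
#' @param fsm_meanlog,fsm_sdlog Log-normal parameters for the school
#'   percentage of pupils eligible for free school meals.
#' @param fsm_threshold Stratification threshold (% FSM, national median).
#' @param participation_rate Probability an invited household is screened.
#' @param screen_positive_rate Target enrolled/screened fraction to which the
#'   screening item thresholds are calibrated.
#' @param decline_rate Probability an eligible selected child does not enrol.
#' @param followup_rate Probability an enrolled child is assessed at 12
#'   months.
#' @param icc_latent Latent-scale outcome ICC in `[0, 1)`; also used for the
#'   mediator's school-level variance share.
#' @param cv_cluster_size Target coefficient of variation of enrolled cluster
#'   sizes.
#' @param mediator_paths List with elements `a` (mediator units per arm
#'   unit), `b` (log-odds per mediator unit) and `c_prime` (direct log-odds).
#' @param baseline_logit Control-arm log-odds of the 12-month outcome.
#' @param complier_probability Probability an enrolled child belongs to the
#'   complier principal stratum (independent of school).
#' @param complier_effect Log-odds effect of intervention for compliers in
#'   the intervention arm (exclusion restriction: zero for never-takers and
#'   for the control arm).
#' @param trait_cor Latent correlation between the three screening
#'   instruments (shared child factor); the trial reports no value, so this
#'   is a configurable assumption, not an asserted truth.
#' @param household_cor Latent correlation between siblings.
#' @param sibling_rate Fraction of invited children sharing a two-child
#'   household.
#' @param missingness MAR specification: list with `measure_rates` (named
#'   vector over `t1`,`t2`,`t3`), `item_rate`, `arm_coef`, `baseline_coef`.
#' @param seed Integer seed; generation is a pure function of
#'   `(config, seed)`.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_schools = 60, classes_per_year = 3,
                       pupils_per_class_mean = 27,
                       fsm_meanlog = log(15.8), fsm_sdlog = 0.55,
                       fsm_threshold = 15.8,
                       participation_rate = 0.17,
                       screen_positive_rate = 0.37,
                       decline_rate = 0.08,
                       followup_rate = 0.80,
                       icc_latent = 0.05,
                       cv_cluster_size = 0.68,
                       mediator_paths = list(a = 0, b = 0, c_prime = 0),
                       baseline_logit = 0,
                       complier_probability = 0.6,
                       complier_effect = -1.05,
                       trait_cor = 0.5,
                       household_cor = 0.3,
                       sibling_rate = 0.04,
                       missingness = list(
                         measure_rates = c(t1 = 0.15, t2 = 0.15, t3 = 0.20),
                         item_rate = 0.02, arm_coef = 0.3,
                         baseline_coef = 0.3),
                       seed = 1) {
  assert_prob(participation_rate, "participation_rate")
  assert_prob(screen_positive_rate, "screen_positive_rate")
  assert_prob(decline_rate, "decline_rate")
  assert_prob(followup_rate, "followup_rate")
  assert_prob(complier_probability, "complier_probability")
  assert_prob(icc_latent, "icc_latent", allow_one = FALSE)
  assert_prob(trait_cor, "trait_cor")
  assert_prob(household_cor, "household_cor")
  assert_prob(sibling_rate, "sibling_rate")
  assert_prob(missingness$measure_rates, "missingness$measure_rates")
  assert_prob(missingness$item_rate, "missingness$item_rate")
  for (v in c(mediator_paths$a, mediator_paths$b, mediator_paths$c_prime,
              baseline_logit, complier_effect, cv_cluster_size)) {
    if (!is.numeric(v) || !is.finite(v)) {
      stop("effect parameters must be finite numbers", call. = FALSE)
    }
  }
  if (cv_cluster_size < 0) stop("cv_cluster_size must be >= 0", call. = FALSE)
  if (n_schools < 1) stop("need at least one school", call. = FALSE)
  cfg <- mget(names(formals(sim_config)), envir = environment())
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic trial cohort
#'
#' Realises the full recruitment funnel: invited children in sampled classes,
#' Bernoulli screening participation (with gamma-distributed school-level
#' heterogeneity so enrolled cluster sizes match the configured coefficient
#' of variation), latent-trait item-level screening responses calibrated to
#' the target enrolment rate, household deduplication (highest PAS, then
#' highest STSC-approach), enrolment, stratified blocked school randomisation
#' ordered by recruited pupil counts, principal-stratum compliance, a
#' continuous mediator with school random effects, and a clustered binary
#' 12-month outcome generated as
#' `logit P(Y=1) = baseline_logit + c'X + bM + complier_effect * X * C + u_school`,
#' with `Var(u_school)` chosen so the latent-scale ICC equals `icc_latent`.
#'
#' @param config A [sim_config()].
#' @return Object of class `"trial_table"`: a list with `master` (one row per
#'   invited child), `items` (item-response tables per timepoint), `schools`
#'   (the allocation roster) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  S <- config$n_schools
  schools <- data.frame(
    school_id = seq_len(S),
    batch = sort(rep_len(1:4, S)),
    fsm_pct = stats::rlnorm(S, config$fsm_meanlog, config$fsm_sdlog)
  )
  schools$fsm_stratum <- ifelse(schools$fsm_pct > config$fsm_threshold,
                                "above", "below")
  # school-level participation heterogeneity inducing the target CV of
  # enrolled cluster sizes: shape = 1 / (cv^2 - 1/mu), mu = expected enrolled
  mu_enrol <- 6 * config$pupils_per_class_mean * config$participation_rate *
    config$screen_positive_rate
  cv2 <- config$cv_cluster_size^2
  shape <- if (mu_enrol > 0 && cv2 > 1 / mu_enrol) 1 / (cv2 - 1 / mu_enrol) else Inf
  g_school <- if (is.finite(shape)) stats::rgamma(S, shape, shape) else rep(1, S)

  # classes: sample exactly two per year group per school
  kids <- list()
  for (j in seq_len(S)) {
    avail <- lapply(1:3, function(y) {
      sprintf("s%03d_y%d_c%d", j, y, seq_len(config$classes_per_year))
    })
    names(avail) <- paste0("year", 1:3)
    sel <- sample_classes(avail, seed = derive_seed(config$seed, 10000 + j))
    for (y in 1:3) {
      for (cl in sel[[y]]) {
        n_pup <- max(5L, stats::rpois(1, config$pupils_per_class_mean))
        kids[[length(kids) + 1]] <- data.frame(
          school_id = j, class_id = cl, year_group = y,
          batch = schools$batch[j], n = n_pup)
      }
    }
  }
  kids <- do.call(rbind, kids)
  master <- kids[rep(seq_len(nrow(kids)), kids$n), c("school_id", "class_id",
                                                     "year_group", "batch")]
  n <- nrow(master)
  master$child_id <- seq_len(n)
  rownames(master) <- NULL
  master <- master[, c("child_id", "school_id", "class_id", "year_group",
                       "batch")]
  master$fsm_pct <- schools$fsm_pct[master$school_id]
  master$fsm_stratum <- schools$fsm_stratum[master$school_id]
  master$gender <- sample(c("female", "male", "other"), n, replace = TRUE,
                          prob = c(0.49, 0.49, 0.02))
  # lower IMD deciles (more deprived) more likely in above-median-FSM schools
  master$imd_decile <- ifelse(
    master$fsm_stratum == "above",
    sample(1:10, n, replace = TRUE, prob = 10:1),
    sample(1:10, n, replace = TRUE, prob = 1:10))

  # households: pair a fraction of children within school into two-child
  # households (siblings in different sampled classes)
  master$household_id <- NA_integer_
  hh_counter <- 0L
  for (j in seq_len(S)) {
    ix <- which(master$school_id == j)
    n_pairs <- floor(length(ix) * config$sibling_rate / 2)
    if (n_pairs > 0) {
      paired <- sample(ix, 2 * n_pairs)
      master$household_id[paired] <- hh_counter +
        rep(seq_len(n_pairs), each = 2)
      hh_counter <- hh_counter + n_pairs
    }
  }
  single <- is.na(master$household_id)
  master$household_id[single] <- hh_counter + seq_len(sum(single))

  # screening participation: one decision per household
  p_part <- pmin(1, config$participation_rate * g_school[master$school_id])
  hh_first <- !duplicated(master$household_id)
  hh_draw <- stats::runif(n)
  hh_u <- stats::ave(ifelse(hh_first, hh_draw, NA), master$household_id,
                     FUN = function(x) x[!is.na(x)][1])
  master$screened <- hh_u < p_part

  # latent traits (household factor, shared child factor, instrument traits)
  hh_norm <- stats::rnorm(max(master$household_id))
  C <- sqrt(config$household_cor) * hh_norm[master$household_id] +
    sqrt(1 - config$household_cor) * stats::rnorm(n)
  insts <- c("pas", "stsc_a", "gad7")
  theta <- lapply(insts, function(i) {
    sqrt(config$trait_cor) * C + sqrt(1 - config$trait_cor) * stats::rnorm(n)
  })
  names(theta) <- insts
  shift <- calibrate_screen_shift(config$screen_positive_rate,
                                  config$trait_cor, config$household_cor,
                                  config$sibling_rate, config$decline_rate)

  scr_ix <- which(master$screened)
  screening <- data.frame(child_id = master$child_id[scr_ix])
  for (i in insts) {
    screening <- cbind(screening, gen_items(theta[[i]][scr_ix], i, shift))
  }
  tot <- lapply(insts, function(i) {
    cols <- grep(paste0("^", i, "_i"), names(screening))
    score_measure(as.matrix(screening[, cols]), i, screening = TRUE)$total
  })
  names(tot) <- insts
  flags <- screen_status(tot$pas, tot$stsc_a, tot$gad7)
  master$pas_screen <- master$stsc_screen <- master$gad7_screen <- NA_real_
  master$pas_screen[scr_ix] <- tot$pas
  master$stsc_screen[scr_ix] <- tot$stsc_a
  master$gad7_screen[scr_ix] <- tot$gad7
  master$screen_positive <- FALSE
  master$screen_positive[scr_ix] <- flags$eligible
  master$risk_child_anxiety <- master$risk_behavioural_inhibition <-
    master$risk_parent_anxiety <- NA
  master$risk_child_anxiety[scr_ix] <- flags$child_anxiety
  master$risk_behavioural_inhibition[scr_ix] <- flags$behavioural_inhibition
  master$risk_parent_anxiety[scr_ix] <- flags$parent_anxiety

  # household deduplication among screen-positive children
  master$household_selected <- master$screen_positive
  pos_ix <- which(master$screen_positive)
  if (length(pos_ix)) {
    dup_hh <- unique(master$household_id[pos_ix][
      duplicated(master$household_id[pos_ix])])
    for (h in dup_hh) {
      cand_ix <- pos_ix[master$household_id[pos_ix] == h]
      cand <- data.frame(child_id = master$child_id[cand_ix],
                         pas = master$pas_screen[cand_ix],
                         stsc_a = master$stsc_screen[cand_ix])
      chosen <- select_household_child(cand)$child_id
      master$household_selected[cand_ix] <- master$child_id[cand_ix] == chosen
    }
  }
  master$enrolled <- master$household_selected &
    stats::runif(n) >= config$decline_rate

  # randomisation: roster of all schools with enrolled pupil counts
  enrol_counts <- tapply(master$enrolled, master$school_id, sum)
  schools$recruited_pupils <- as.integer(enrol_counts[as.character(
    schools$school_id)])
  schools$recruited_pupils[is.na(schools$recruited_pupils)] <- 0L
  alloc <- generate_allocation(schools, seed = derive_seed(config$seed, 2))
  arm_by_school <- stats::setNames(alloc$arm, alloc$school_id)
  master$arm <- ifelse(master$enrolled,
                       arm_by_school[as.character(master$school_id)],
                       NA_integer_)
  master$cluster_size <- as.integer(enrol_counts[as.character(
    master$school_id)])

  # principal strata and module completion
  enr_ix <- which(master$enrolled)
  master$complier_stratum <- NA_integer_
  master$complier_stratum[enr_ix] <-
    stats::rbinom(length(enr_ix), 1, config$complier_probability)
  master$modules_completed <- ifelse(master$enrolled, 0L, NA_integer_)
  iv_c <- which(master$enrolled & master$arm == 1 &
                  master$complier_stratum == 1)
  iv_n <- which(master$enrolled & master$arm == 1 &
                  master$complier_stratum == 0)
  master$modules_completed[iv_c] <- sample(5:8, length(iv_c), replace = TRUE)
  master$modules_completed[iv_n] <- sample(0:4, length(iv_n), replace = TRUE)

  # mediator and outcome with school random effects on the latent scale
  icc <- config$icc_latent
  sd_u <- sqrt(icc / (1 - icc) * pi^2 / 3)
  sd_v <- sqrt(icc / (1 - icc))
  u_school <- stats::rnorm(S, 0, sd_u)
  v_school <- stats::rnorm(S, 0, sd_v)
  paths <- config$mediator_paths
  master$mediator_latent <- NA_real_
  master$outcome_latent <- NA_real_
  master$anxiety_disorder_12m <- NA_integer_
  arm_e <- master$arm[enr_ix]
  M <- paths$a * arm_e + v_school[master$school_id[enr_ix]] +
    stats::rnorm(length(enr_ix))
  eta <- config$baseline_logit + paths$c_prime * arm_e + paths$b * M +
    config$complier_effect * arm_e * master$complier_stratum[enr_ix] +
    u_school[master$school_id[enr_ix]]
  latent <- eta + stats::rlogis(length(enr_ix))
  master$mediator_latent[enr_ix] <- M
  master$outcome_latent[enr_ix] <- latent
  y12 <- as.integer(latent > 0)

  master$followed_up_12m <- NA
  master$followed_up_12m[enr_ix] <-
    stats::runif(length(enr_ix)) < config$followup_rate
  master$fu_weeks_late <- NA_real_
  fu_ix <- which(master$enrolled & master$followed_up_12m)
  master$fu_weeks_late[fu_ix] <- round(stats::rexp(length(fu_ix), 1 / 4), 1)
  master$anxiety_disorder_12m[enr_ix] <- ifelse(master$followed_up_12m[enr_ix],
                                                y12, NA_integer_)

  # follow-up item responses for enrolled children; instrument traits track
  # the screening trait (or the shared child factor) plus the mediator at
  # 12 weeks, so scored totals carry the generated paths
  items <- list(screening = screening)
  M_all <- rep(NA_real_, n)
  M_all[enr_ix] <- M
  base_trait <- list()
  for (i in names(.item_base_probs)) {
    base_trait[[i]] <- if (i %in% insts) {
      0.8 * theta[[i]] + 0.6 * stats::rnorm(n)
    } else {
      sqrt(config$trait_cor) * C + sqrt(1 - config$trait_cor) * stats::rnorm(n)
    }
  }
  for (tp in names(.schedule)) {
    row_ix <- if (tp == "t3") fu_ix else enr_ix
    if (!length(row_ix)) {
      items[[tp]] <- data.frame(child_id = integer(0))
      next
    }
    tab <- data.frame(child_id = master$child_id[row_ix])
    for (i in .schedule[[tp]]) {
      tr <- base_trait[[i]][row_ix] + 0.5 * stats::rnorm(length(row_ix))
      if (tp == "t2") tr <- tr + 0.4 * (M_all[row_ix] - paths$a / 2)
      tab <- cbind(tab, gen_items(tr, i, shift))
    }
    items[[tp]] <- tab
  }

  structure(list(master = master, items = items,
                 schools = alloc, config = config),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  fc <- funnel_counts(x)
  cat("Synthetic trial table\n")
  print(fc)
  invisible(x)
}

#' CONSORT-style funnel counts
#'
#' Counts children at each recruitment stage, overall and (from enrolment
#' onwards, when arms exist) by allocated arm. Counts are non-increasing
#' along the funnel.
#'
#' @param table A `trial_table`.
#' @return Data frame with columns `stage`, `overall`, `control`,
#'   `intervention` (NA before randomisation).
#' @export
funnel_counts <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master
  n_arm <- function(flag, a) sum(flag & !is.na(m$arm) & m$arm == a, na.rm = TRUE)
  stages <- list(
    invited = rep(TRUE, nrow(m)),
    screened = m$screened,
    screen_positive = m$screen_positive,
    enrolled = m$enrolled,
    followed_up = m$enrolled & !is.na(m$followed_up_12m) & m$followed_up_12m
  )
  out <- data.frame(
    stage = names(stages),
    overall = vapply(stages, function(f) sum(f, na.rm = TRUE), 1),
    control = vapply(stages, function(f) n_arm(f, 0), 1),
    intervention = vapply(stages, function(f) n_arm(f, 1), 1)
  )
  out$control[1:3] <- NA
  out$intervention[1:3] <- NA
  rownames(out) <- NULL
  out
}

#' Analysis-ready child-level dataset
#'
#' Extracts enrolled children with identifiers, design variables, screening
#' totals, latent simulation fields, compliance and the 12-month outcome, plus
#' scored instrument totals (wide, `<instrument>_<timepoint>`) for use by the
#' estimation, mediation and CACE modules.
#'
#' @param table A `trial_table`.
#' @param instruments Instruments to score and merge (default PAS only, the
#'   designated mediator instrument; use more for secondary outcomes).
#' @return Data frame, one row per enrolled child.
#' @export
analysis_data <- function(table, instruments = "pas") {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master[table$master$enrolled, , drop = FALSE]
  sc <- score_table(table)
  sc <- sc[sc$instrument %in% instruments & sc$timepoint != "screening", ]
  for (i in unique(sc$instrument)) {
    for (tp in unique(sc$timepoint[sc$instrument == i])) {
      v <- sc[sc$instrument == i & sc$timepoint == tp, ]
      m[[paste0(i, "_", tp)]] <- v$total[match(m$child_id, v$child_id)]
    }
  }
  m$complier <- classify_complier(m$modules_completed, m$arm)
  rownames(m) <- NULL
  m
}

#' Light-weight clustered outcome simulator for method studies
#'
#' Generates an enrolled-cohort dataset directly (no screening funnel): a
#' two-arm cluster design with school random effects on the latent logistic
#' scale, optional principal-stratum compliance, and an optional continuous
#' mediator. Used for simulation-based validation of the estimation,
#' mediation and CACE machinery at controlled problem sizes.
#'
#' @param n_schools Number of schools (split 1:1 between arms).
#' @param cluster_size Mean cluster size.
#' @param cluster_size_cv Coefficient of variation of cluster sizes (0 =
#'   fixed; otherwise negative-binomial sizes).
#' @param icc Latent-scale ICC.
#' @param baseline_logit Control-arm log-odds.
#' @param arm_logodds Direct arm effect (log-odds, applies to everyone).
#' @param complier_logodds Additional log-odds effect for compliers in the
#'   intervention arm.
#' @param complier_probability Complier-stratum probability.
#' @param mediator_a,mediator_b Mediation paths (arm -> mediator in SD units;
#'   mediator -> outcome in log-odds).
#' @param seed Integer seed.
#' @return Data frame with `school_id`, `arm`, `fsm_stratum`, `cluster_size`,
#'   `gender`, `year_group`, `batch`, `imd_decile`, `complier_stratum`,
#'   `modules_completed`, `complier`, `mediator`, `outcome_latent`, `y`.
#' @export
simulate_outcome_data <- function(n_schools = 60, cluster_size = 10,
                                  cluster_size_cv = 0, icc = 0.05,
                                  baseline_logit = 0, arm_logodds = 0,
                                  complier_logodds = 0,
                                  complier_probability = 1,
                                  mediator_a = 0, mediator_b = 0, seed = 1) {
  assert_prob(icc, "icc", allow_one = FALSE)
  with_seed(seed, {
    sizes <- if (cluster_size_cv > 0) {
      v <- (cluster_size_cv * cluster_size)^2
      theta <- cluster_size^2 / max(v - cluster_size, 1e-8)
      pmax(1L, stats::rnbinom(n_schools, mu = cluster_size, size = theta))
    } else rep(as.integer(round(cluster_size)), n_schools)
    arm_school <- sample(rep_len(0:1, n_schools))
    school <- rep(seq_len(n_schools), sizes)
    n <- length(school)
    sd_u <- sqrt(icc / (1 - icc) * pi^2 / 3)
    sd_v <- sqrt(icc / (1 - icc))
    u <- stats::rnorm(n_schools, 0, sd_u)
    v <- stats::rnorm(n_schools, 0, sd_v)
    arm <- arm_school[school]
    comp <- stats::rbinom(n, 1, complier_probability)
    M <- mediator_a * arm + v[school] + stats::rnorm(n)
    eta <- baseline_logit + arm_logodds * arm + mediator_b * M +
      complier_logodds * arm * comp + u[school]
    latent <- eta + stats::rlogis(n)
    fsm <- sample(c("above", "below"), n_schools, replace = TRUE)
    modules <- integer(n)
    modules[arm == 1 & comp == 1] <- sample(5:8, sum(arm == 1 & comp == 1),
                                            replace = TRUE)
    modules[arm == 1 & comp == 0] <- sample(0:4, sum(arm == 1 & comp == 0),
                                            replace = TRUE)
    data.frame(
      child_id = seq_len(n), school_id = school, arm = arm,
      fsm_stratum = fsm[school], cluster_size = sizes[school],
      gender = sample(c("female", "male"), n, replace = TRUE),
      year_group = sample(1:3, n, replace = TRUE),
      batch = rep_len(1:4, n_schools)[school],
      imd_decile = sample(1:10, n, replace = TRUE),
      complier_stratum = comp, modules_completed = modules,
      complier = as.integer(arm == 1 & modules >= 5),
      mediator = M, outcome_latent = latent, y = as.integer(latent > 0))
  })
}
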