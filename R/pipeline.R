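# End-to-end pipeline: simulate -> score -> impose missingness -> impute ->
# analyse -> mediate -> CACE -> report, with counter-based sub-seeds derived
# from a single global seed and a manifest of stage digests.

#' Pipeline configuration
#'
#' @param seed Global seed; each stage derives its own sub-seed by a
#'   counter-based scheme ([derive_seed()]), so re-running one stage gives
#'   the same result regardless of the order stages execute in.
#' @param dir Optional output directory; `NULL` keeps everything in memory.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("simulate", "missingness", "impute", "analyse", "mediate", "cace",
#'   "report")`.
#' @param sim A [sim_config()]; its seed is overwritten by the derived
#'   sub-seed.
#' @param m Number of imputed datasets.
#' @param imputation_burnin,imputation_thin Gibbs controls.
#' @param bootstrap_reps CACE bootstrap replicates.
#' @param mediator Mediator column for the mediation stage (a scored
#'   12-week total produced by [analysis_data()], e.g. `"pas_t2"`).
#' @param mcmc_chains,mcmc_iter,mcmc_warmup Mediation MCMC controls.
#' @param adjust Adjustment covariate set used by the analysis, mediation and
#'   CACE stages.
#' @param reduced Reduced-scale mode: shrinks the simulation and MCMC sizes
#'   for fast smoke runs (10 schools, m = 5, 200 bootstrap replicates).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, dir = NULL,
                            stages = c("simulate", "missingness", "impute",
                                       "analyse", "mediate", "cace",
                                       "report"),
                            sim = sim_config(),
                            m = 50, imputation_burnin = 1000,
                            imputation_thin = 100,
                            bootstrap_reps = 1000,
                            mediator = "pas_t2",
                            mcmc_chains = 4, mcmc_iter = 1000,
                            mcmc_warmup = 500,
                            adjust = c("fsm_stratum", "cluster_size",
                                       "gender", "year_group", "batch",
                                       "imd_decile"),
                            reduced = FALSE) {
  known <- c("simulate", "missingness", "impute", "analyse", "mediate",
             "cace", "report")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  if (reduced) {
    sim$n_schools <- 10
    m <- 5
    imputation_burnin <- 100
    imputation_thin <- 10
    bootstrap_reps <- 200
    mcmc_chains <- 2
    mcmc_iter <- 400
    mcmc_warmup <- 300
    # a 10-school run cannot support the full school-level adjustment set
    adjust <- c("fsm_stratum", "imd_decile", "gender")
  }
  structure(list(seed = seed, dir = dir, stages = stages, sim = sim, m = m,
                 imputation_burnin = imputation_burnin,
                 imputation_thin = imputation_thin,
                 bootstrap_reps = bootstrap_reps, mediator = mediator,
                 mcmc_chains = mcmc_chains, mcmc_iter = mcmc_iter,
                 mcmc_warmup = mcmc_warmup, adjust = adjust,
                 reduced = reduced),
            class = "pipeline_config")
}

require_stage <- function(artefacts, what, needed_by) {
  if (is.null(artefacts[[what]])) {
    stop(sprintf("stage '%s' requires the '%s' stage output, which is disabled or missing",
                 needed_by, what), call. = FALSE)
  }
  artefacts[[what]]
}

need_table <- function(tab, needed_by) {
  if (is.null(tab)) {
    stop(sprintf("stage '%s' requires the simulated trial table, but the 'simulate' stage is disabled",
                 needed_by), call. = FALSE)
  }
  tab
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort and returns an
#' artefact bundle with a manifest of per-stage seeds and content digests.
#' Any stage failure halts the run with an error naming the stage; stages
#' whose upstream inputs are disabled fail fast with a dependency error.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_result"` with stage artefacts and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  art <- list()
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, seed, obj) {
    manifest$stages[[stage]] <<- list(seed = seed, digest = content_digest(obj))
  }
  on <- function(s) s %in% config$stages

  if (on("simulate")) {
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, 1)
    art$simulate <- generate_cohort(cfg)
    note("simulate", cfg$seed, art$simulate$master)
  }
  if (on("missingness")) {
    tt <- require_stage(art, "simulate", "missingness")
    cfg <- tt$config
    cfg$seed <- derive_seed(config$seed, 2)
    art$missingness <- impose_missingness(tt, cfg)
    note("missingness", cfg$seed, art$missingness$items)
  }
  current_table <- art$missingness %||% art$simulate
  if (on("impute")) {
    tt <- need_table(current_table, "impute")
    adat <- analysis_data(tt)
    vars <- c("anxiety_disorder_12m", "arm", "fsm_stratum", "cluster_size",
              "imd_decile", "pas_t0", "pas_t2", "modules_completed")
    vars <- intersect(vars, names(adat))
    ispec <- imputation_spec(
      variables = vars, binary = "anxiety_disorder_12m",
      categorical = list(fsm_stratum = c("above", "below")),
      m = config$m, burnin = config$imputation_burnin,
      thin = config$imputation_thin, seed = derive_seed(config$seed, 3))
    state <- fit_joint_model(adat, ispec)
    art$impute <- draw_imputations(state)
    note("impute", ispec$seed, lapply(art$impute$datasets, `[[`,
                                      "anxiety_disorder_12m"))
  }
  if (on("analyse")) {
    if (!is.null(art$impute)) {
      fits <- lapply(art$impute$datasets, function(d) {
        fit_primary_binary(d, analysis_spec(adjust = config$adjust))
      })
      art$analyse <- pool_rubin(vapply(fits, `[[`, 1, "log_estimate"),
                                vapply(fits, `[[`, 1, "se"), log = TRUE)
    } else {
      tt <- need_table(current_table, "analyse")
      art$analyse <- fit_primary_binary(analysis_data(tt),
                                        analysis_spec(adjust = config$adjust))
    }
    note("analyse", NA, unclass(art$analyse)[c("estimate", "se")])
  }
  if (on("mediate")) {
    datasets <- if (!is.null(art$impute)) art$impute$datasets else {
      tt <- need_table(current_table, "mediate")
      list(analysis_data(tt))
    }
    mspec <- mediation_spec(config$mediator, baseline = "pas_t0",
                            covariates = config$adjust,
                            chains = config$mcmc_chains,
                            iter = config$mcmc_iter,
                            warmup = config$mcmc_warmup,
                            seed = derive_seed(config$seed, 4))
    art$mediate <- suppressWarnings(mediate(datasets, mspec))
    note("mediate", mspec$seed, art$mediate$summary)
  }
  if (on("cace")) {
    datasets <- if (!is.null(art$impute)) art$impute$datasets else {
      tt <- need_table(current_table, "cace")
      list(analysis_data(tt))
    }
    seed_c <- derive_seed(config$seed, 5)
    results <- lapply(seq_along(datasets), function(i) {
      cace_analysis(datasets[[i]], covariates = config$adjust,
                    bootstrap_reps = config$bootstrap_reps,
                    seed = derive_seed(seed_c, i))
    })
    art$cace <- if (length(results) > 1) pool_cace(results) else results[[1]]
    attr(art$cace, "per_imputation") <- results
    note("cace", seed_c,
         if (inherits(art$cace, "pooled_estimate")) {
           list(art$cace$estimate, art$cace$se)
         } else list(art$cace$beta1, art$cace$se))
  }
  if (on("report")) {
    tt <- need_table(current_table, "report")
    art$report <- list(flow = build_flow(tt),
                       baseline = baseline_table(tt),
                       missingness = missingness_summary(tt),
                       nonparticipants = nonparticipant_comparison(tt))
    note("report", NA, art$report$flow$funnel)
  }
  art$manifest <- manifest
  if (!is.null(config$dir)) {
    dir.create(config$dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(current_table)) {
      write_trial_table(current_table, file.path(config$dir, "trial"))
    }
    jsonlite::write_json(manifest, file.path(config$dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(art$report)) {
      utils::write.csv(art$report$flow$funnel,
                       file.path(config$dir, "funnel.csv"), row.names = FALSE)
      utils::write.csv(art$report$baseline,
                       file.path(config$dir, "baseline.csv"),
                       row.names = FALSE)
      utils::write.csv(art$report$missingness,
                       file.path(config$dir, "missingness.csv"),
                       row.names = FALSE)
    }
  }
  structure(art, class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
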