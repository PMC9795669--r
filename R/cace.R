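# Complier average causal effect by two-stage residual inclusion:
# stage 1 regresses compliance on arm (random-intercept linear model);
# stage 2 is a marginal logistic GEE of the outcome on compliance status and
# the stage-1 residual totals, with cluster bootstrap SEs and Rubin pooling
# across imputed datasets.

#' Classify compliance with the intervention
#'
#' A participant is a complier if they completed at least the first five
#' online modules (modules 0-4), i.e. `modules_completed >= 5`. Control-arm
#' participants cannot access the modules, so their count is 0 and they are
#' never classified as compliers.
#'
#' @param modules_completed Integer count of completed modules in `[0, 8]`.
#' @param arm Allocated arm (0 control / 1 intervention); `NULL` to classify
#'   from the count alone.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' classify_complier(5, 1)  # 1
#' classify_complier(4, 1)  # 0
classify_complier <- function(modules_completed, arm = NULL) {
  if (any(modules_completed < 0, na.rm = TRUE)) {
    stop("negative module count", call. = FALSE)
  }
  if (any(modules_completed > 8, na.rm = TRUE)) {
    stop("module count above 8", call. = FALSE)
  }
  out <- as.integer(modules_completed >= 5)
  if (!is.null(arm)) out[!is.na(arm) & arm == 0] <- 0L
  out
}

#' Stage 1: compliance regressed on arm with school random effects
#'
#' Random-effects *linear* (not logistic) regression of compliance status on
#' trial arm and the stage-1 covariates. Returns the fitted model and the
#' per-child residual totals — the sum of the estimated cluster effect and
#' the individual residual, i.e. observed compliance minus the fixed-effects
#' prediction.
#'
#' @param data Analysis data frame with `complier`, `arm`, `school_id` and
#'   the covariates.
#' @param covariates Stage-1 adjustment set Z1 (constant or missing columns
#'   are dropped).
#' @return List with `fit`, `beta_arm` (first-stage coefficient),
#'   `beta_arm_se`, `residual_totals` (aligned to rows of `data`),
#'   `ranef_sd`.
#' @export
stage1_compliance <- function(data,
                              covariates = c("fsm_stratum", "cluster_size",
                                             "gender", "year_group", "batch",
                                             "imd_decile")) {
  if (length(unique(data$arm[!is.na(data$arm)])) < 2) {
    stop("both arms required", call. = FALSE)
  }
  if (length(unique(data$school_id)) < 2) {
    stop("need >= 2 schools", call. = FALSE)
  }
  if (stats::var(data$complier[data$arm == 1]) == 0 &&
      all(data$complier[data$arm == 1] == 0)) {
    stop("no compliance variation in the intervention arm", call. = FALSE)
  }
  covariates <- covariates[vapply(covariates, function(v) {
    v %in% names(data) && length(unique(data[[v]][!is.na(data[[v]])])) > 1
  }, TRUE)]
  f <- stats::as.formula(paste("complier ~ arm",
                               if (length(covariates)) {
                                 paste("+", paste(covariates, collapse = " + "))
                               } else "", "+ (1 | school_id)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(f, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  fixed_pred <- stats::predict(fit, newdata = data, re.form = NA)
  res_tot <- data$complier - fixed_pred
  vc <- as.data.frame(lme4::VarCorr(fit))
  se_arm <- tryCatch(
    sqrt(suppressWarnings(as.matrix(stats::vcov(fit)))["arm", "arm"]),
    error = function(e) NA_real_)  # degenerate (zero-residual) fits
  list(fit = fit,
       beta_arm = lme4::fixef(fit)[["arm"]],
       beta_arm_se = se_arm,
       residual_totals = res_tot,
       ranef_sd = sqrt(vc$vcov[vc$grp == "school_id"]))
}

#' Stage 2: outcome model with residual inclusion
#'
#' Marginal logistic GEE (exchangeable working correlation, robust SEs,
#' clustered on school) of the binary outcome on compliance status, the
#' stage-1 residual totals and the pre-specified covariates. The coefficient
#' on compliance, `beta1`, is the CACE on the log-odds scale. If the
#' residual totals are numerically constant (the full-compliance limit,
#' where compliance equals arm and the residuals vanish) the residual
#' covariate is dropped and `beta2` is `NA`; the model then coincides with
#' the intention-to-treat model.
#'
#' @param data Analysis data frame with the outcome.
#' @param stage1 Result of [stage1_compliance()] on the same rows.
#' @param outcome Binary outcome column.
#' @param covariates Stage-2 adjustment set Z2 (the primary-analysis set).
#' @return List with `beta1`, `beta1_se` (robust), `beta2`, `fit`.
#' @export
stage2_outcome <- function(data, stage1, outcome = "anxiety_disorder_12m",
                           covariates = c("fsm_stratum", "cluster_size",
                                          "gender", "year_group", "batch",
                                          "imd_decile")) {
  if (length(stage1$residual_totals) != nrow(data)) {
    stop("stage-1 residuals not aligned to data rows", call. = FALSE)
  }
  d <- data
  d$.resid_c <- stage1$residual_totals
  keep_resid <- stats::sd(d$.resid_c, na.rm = TRUE) > 1e-8
  covariates <- covariates[vapply(covariates, function(v) {
    v %in% names(d) && length(unique(d[[v]][!is.na(d[[v]])])) > 1
  }, TRUE)]
  rhs <- c("complier", if (keep_resid) ".resid_c", covariates)
  f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- gee_logit(f, d, cluster = "school_id")
  list(beta1 = fit$coefficients[["complier"]],
       beta1_se = sqrt(fit$robust.vcov["complier", "complier"]),
       beta2 = if (keep_resid) fit$coefficients[[".resid_c"]] else NA_real_,
       fit = fit)
}

# Run both stages on one dataset; used directly and inside the bootstrap.
run_2sri <- function(data, outcome, covariates) {
  s1 <- stage1_compliance(data, covariates)
  s2 <- stage2_outcome(data, s1, outcome, covariates)
  list(stage1 = s1, stage2 = s2)
}

#' Cluster bootstrap for the CACE estimator
#'
#' Resamples schools with replacement — stratified by arm, preserving the
#' 1:1 design — and reruns the full two-stage procedure on each replicate.
#' Returns the bootstrap SE (SD of replicate `beta1`) and the percentile
#' 95% CI. Replicates that fail (e.g. degenerate resamples) are dropped and
#' counted.
#'
#' @param data Analysis data frame.
#' @param reps Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param outcome,covariates Passed to the two stages.
#' @param max_failure_rate Error if more than this fraction of replicates
#'   fails.
#' @return List with `se`, `ci` (percentile), `reps_used`, `failures`,
#'   `replicates`.
#' @export
cluster_bootstrap <- function(data, reps = 1000, seed = 1,
                              outcome = "anxiety_disorder_12m",
                              covariates = c("fsm_stratum", "cluster_size",
                                             "gender", "year_group", "batch",
                                             "imd_decile"),
                              max_failure_rate = 0.1) {
  if (reps < 100) stop("need at least 100 bootstrap replicates", call. = FALSE)
  arm_by_school <- tapply(data$arm, data$school_id, max)
  schools_by_arm <- split(names(arm_by_school), arm_by_school)
  rows_by_school <- split(seq_len(nrow(data)), data$school_id)
  b1 <- rep(NA_real_, reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      res <- tryCatch({
        take <- unlist(lapply(schools_by_arm, function(s) {
          sample(s, length(s), replace = TRUE)
        }))
        idx <- unlist(lapply(seq_along(take), function(i) {
          rows_by_school[[as.character(take[i])]]
        }))
        d <- data[idx, , drop = FALSE]
        # resampled schools become distinct pseudo-clusters
        d$school_id <- rep(seq_along(take), vapply(take, function(s) {
          length(rows_by_school[[as.character(s)]])
        }, 1L))
        run_2sri(d, outcome, covariates)$stage2$beta1
      }, error = function(e) NA_real_)
      b1[r] <- res
    }
  })
  failures <- sum(is.na(b1))
  if (failures / reps > max_failure_rate) {
    stop(sprintf("bootstrap failure rate %.1f%% exceeds the configured %.1f%%",
                 100 * failures / reps, 100 * max_failure_rate),
         call. = FALSE)
  }
  ok <- b1[!is.na(b1)]
  list(se = stats::sd(ok),
       ci = stats::quantile(ok, c(0.025, 0.975), names = FALSE),
       reps_used = length(ok), failures = failures, replicates = ok)
}

#' Complete CACE analysis on one dataset
#'
#' Runs the two-stage residual-inclusion procedure, optionally with a
#' cluster bootstrap for the standard error, and reports the first-stage
#' instrument strength (a weak-instrument warning is issued below the
#' configurable threshold) and compliance rates by arm.
#'
#' @param data Analysis data frame with `complier`, `arm`, `school_id` and
#'   the outcome.
#' @param outcome Binary outcome column.
#' @param covariates Adjustment set used at both stages.
#' @param bootstrap_reps Replicates for [cluster_bootstrap()] (0 skips it).
#' @param seed Integer seed for the bootstrap.
#' @param weak_threshold Warn if the first-stage arm coefficient is below
#'   this value.
#' @return Object of class `"cace_result"` with `beta1`, `beta2`, robust and
#'   bootstrap SEs, CIs, stage-1 summaries and compliance rates.
#' @export
cace_analysis <- function(data, outcome = "anxiety_disorder_12m",
                          covariates = c("fsm_stratum", "cluster_size",
                                         "gender", "year_group", "batch",
                                         "imd_decile"),
                          bootstrap_reps = 1000, seed = 1,
                          weak_threshold = 0.1) {
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (!"complier" %in% names(data)) {
    data$complier <- classify_complier(data$modules_completed, data$arm)
  }
  fits <- run_2sri(data, outcome, covariates)
  if (fits$stage1$beta_arm < weak_threshold) {
    warning(sprintf("weak instrument: first-stage coefficient %.3f < %.2f",
                    fits$stage1$beta_arm, weak_threshold), call. = FALSE)
  }
  boot <- NULL
  if (bootstrap_reps > 0) {
    boot <- cluster_bootstrap(data, reps = bootstrap_reps, seed = seed,
                              outcome = outcome, covariates = covariates)
  }
  comp_rate <- tapply(data$complier, data$arm, mean)
  se <- if (!is.null(boot)) boot$se else fits$stage2$beta1_se
  structure(list(
    beta1 = fits$stage2$beta1, beta2 = fits$stage2$beta2,
    robust_se = fits$stage2$beta1_se,
    bootstrap = boot, se = se,
    ci = if (!is.null(boot)) boot$ci else
      fits$stage2$beta1 + c(-1, 1) * 1.96 * fits$stage2$beta1_se,
    or = exp(fits$stage2$beta1),
    stage1_beta = fits$stage1$beta_arm,
    stage1_se = fits$stage1$beta_arm_se,
    compliance_by_arm = comp_rate,
    n = nrow(data), seed = seed),
    class = "cace_result")
}

#' @export
print.cace_result <- function(x, ...) {
  cat(sprintf("CACE log-odds beta1 = %.4f (OR %.3f), SE = %.4f\n",
              x$beta1, x$or, x$se))
  cat(sprintf("  95%% CI (%.4f, %.4f); first-stage coefficient %.3f (SE %.3f)\n",
              x$ci[1], x$ci[2], x$stage1_beta, x$stage1_se))
  cat(sprintf("  compliance: control %.2f, intervention %.2f; n = %d\n",
              x$compliance_by_arm[["0"]], x$compliance_by_arm[["1"]], x$n))
  invisible(x)
}

#' Pool CACE estimates across imputed datasets
#'
#' Rubin's rules applied to the per-imputation `beta1` estimates with the
#' bootstrap-based within-imputation variances.
#'
#' @param results List of `"cace_result"` objects (>= 2), each with a
#'   bootstrap (or robust) SE.
#' @return A [pool_rubin()] `"pooled_estimate"` on the log-odds scale, with
#'   `or` and `or_ci` attached.
#' @export
pool_cace <- function(results) {
  if (length(results) < 2) stop("need >= 2 imputations", call. = FALSE)
  est <- vapply(results, `[[`, 1, "beta1")
  ses <- vapply(results, `[[`, 1, "se")
  if (any(is.na(ses))) stop("missing standard errors", call. = FALSE)
  pooled <- pool_rubin(est, ses)
  pooled$or <- exp(pooled$estimate)
  pooled$or_ci <- exp(pooled$ci)
  pooled
}
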