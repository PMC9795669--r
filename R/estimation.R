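# Intention-to-treat estimation: marginal logistic GEE for the binary
# primary outcome, random-intercept linear models for continuous secondary
# outcomes, ICC reporting, Rubin pooling, moderator interaction tests and
# the within-window sensitivity filter.

#' Analysis specification
#'
#' @param outcome Outcome column name.
#' @param type `"binary"` or `"continuous"`.
#' @param baseline Baseline-outcome column (continuous outcomes only;
#'   `NULL` if unavailable).
#' @param adjust Adjustment covariates. The pre-specified set is the
#'   stratification factor (`fsm_stratum`), recruited cluster size as a
#'   continuous variable (its role in the randomisation), `gender`,
#'   `year_group`, `batch` (cohort) and `imd_decile` as a continuous measure
#'   of socioeconomic status.
#' @param crude If `TRUE`, fit the unadjusted model (arm only).
#' @param population `"imputed"`, `"complete-case"` or `"within-window"`.
#' @return Object of class `"analysis_spec"`.
#' @export
analysis_spec <- function(outcome = "anxiety_disorder_12m",
                          type = c("binary", "continuous"),
                          baseline = NULL,
                          adjust = c("fsm_stratum", "cluster_size", "gender",
                                     "year_group", "batch", "imd_decile"),
                          crude = FALSE,
                          population = c("imputed", "complete-case",
                                        "within-window")) {
  type <- match.arg(type)
  population <- match.arg(population)
  structure(list(outcome = outcome, type = type, baseline = baseline,
                 adjust = adjust, crude = crude, population = population),
            class = "analysis_spec")
}

build_formula <- function(spec, extra = "arm") {
  rhs <- if (spec$crude) extra else {
    paste(c(extra, spec$baseline, spec$adjust), collapse = " + ")
  }
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

# keep only covariates that vary in the supplied data (degenerate factors
# would make the design matrix singular on small subsets)
drop_constant_terms <- function(spec, data) {
  keep <- vapply(spec$adjust, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) > 1
  }, TRUE)
  spec$adjust <- spec$adjust[keep]
  spec
}

#' Primary intention-to-treat analysis of a binary outcome
#'
#' Marginal logistic model fitted by GEE with an exchangeable working
#' correlation clustered on school and robust (sandwich) standard errors.
#' The intervention effect is reported as an odds ratio with a 95% CI and
#' p-value; crude and adjusted latent-scale ICCs are attached when
#' `include_icc = TRUE`.
#'
#' @param data Child-level analysis data frame (see [analysis_data()]) with
#'   columns `arm`, `school_id`, the outcome and any adjustment covariates.
#' @param spec An [analysis_spec()] with `type = "binary"`.
#' @param include_icc Also fit random-intercept logistic models to report
#'   crude and adjusted ICCs (slower).
#' @return Object of class `"effect_estimate"`.
#' @export
fit_primary_binary <- function(data, spec = analysis_spec(),
                               include_icc = FALSE) {
  stopifnot(inherits(spec, "analysis_spec"), spec$type == "binary")
  data <- data[!is.na(data[[spec$outcome]]), , drop = FALSE]
  if (nrow(data) == 0) stop("all outcome values missing", call. = FALSE)
  if (length(unique(data$arm[!is.na(data$arm)])) < 2) {
    stop("need both arms present", call. = FALSE)
  }
  spec <- drop_constant_terms(spec, data)
  fit <- gee_logit(build_formula(spec), data, cluster = "school_id")
  b <- fit$coefficients[["arm"]]
  se <- sqrt(fit$robust.vcov["arm", "arm"])
  ci <- b + c(-1, 1) * stats::qnorm(0.975) * se
  icc_crude <- icc_adj <- NA_real_
  if (include_icc) {
    icc_crude <- estimate_icc(data, spec$outcome, type = "binary",
                              adjusted = FALSE, spec = spec)
    icc_adj <- estimate_icc(data, spec$outcome, type = "binary",
                            adjusted = TRUE, spec = spec)
  }
  structure(list(scale = "odds ratio", outcome = spec$outcome,
                 estimate = exp(b), log_estimate = b, se = se,
                 ci = exp(ci), p = 2 * stats::pnorm(-abs(b / se)),
                 n = fit$n, n_clusters = fit$n_clusters,
                 icc_crude = icc_crude, icc_adjusted = icc_adj,
                 fit = fit),
            class = "effect_estimate")
}

#' Secondary analysis of a continuous outcome
#'
#' Random-intercept (school) linear model. Reports the adjusted mean
#' difference, its 95% CI and p-value, and a standardised mean difference
#' (mean difference divided by the pooled baseline SD of the outcome; when no
#' baseline measure exists, the pooled outcome SD is used).
#'
#' @param data Analysis data frame.
#' @param spec An [analysis_spec()] with `type = "continuous"` and the
#'   baseline column named in `baseline` where available.
#' @param include_icc Report crude/adjusted ICCs from variance components.
#' @return Object of class `"effect_estimate"`.
#' @export
fit_secondary_continuous <- function(data, spec, include_icc = FALSE) {
  stopifnot(inherits(spec, "analysis_spec"), spec$type == "continuous")
  data <- data[!is.na(data[[spec$outcome]]), , drop = FALSE]
  if (stats::sd(data[[spec$outcome]]) == 0) {
    stop("outcome has zero variance", call. = FALSE)
  }
  spec <- drop_constant_terms(spec, data)
  f <- stats::update(build_formula(spec), . ~ . + (1 | school_id))
  fit <- lme4::lmer(f, data = data, REML = TRUE)
  b <- lme4::fixef(fit)[["arm"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["arm", "arm"])
  sd_base <- if (!is.null(spec$baseline) && spec$baseline %in% names(data)) {
    stats::sd(data[[spec$baseline]], na.rm = TRUE)
  } else {
    stats::sd(data[[spec$outcome]], na.rm = TRUE)
  }
  icc_crude <- icc_adj <- NA_real_
  if (include_icc) {
    icc_crude <- estimate_icc(data, spec$outcome, type = "continuous",
                              adjusted = FALSE, spec = spec)
    icc_adj <- estimate_icc(data, spec$outcome, type = "continuous",
                            adjusted = TRUE, spec = spec)
  }
  structure(list(scale = "mean difference", outcome = spec$outcome,
                 estimate = b, se = se,
                 ci = b + c(-1, 1) * stats::qnorm(0.975) * se,
                 p = 2 * stats::pnorm(-abs(b / se)),
                 smd = b / sd_base, n = stats::nobs(fit),
                 icc_crude = icc_crude, icc_adjusted = icc_adj,
                 fit = fit),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s [%s]: %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
              x$outcome, x$scale, x$estimate, x$ci[1], x$ci[2], x$p, x$n))
  if (!is.na(x$icc_crude)) {
    cat(sprintf("  ICC crude %.3f, adjusted %.3f\n", x$icc_crude,
                x$icc_adjusted))
  }
  if (!is.null(x$smd)) cat(sprintf("  standardised mean difference %.3f\n",
                                   x$smd))
  invisible(x)
}

#' Intra-cluster correlation coefficient
#'
#' For continuous outcomes, the variance-partition ICC from a
#' random-intercept linear model (optionally covariate-adjusted). For binary
#' outcomes, the latent-threshold-scale ICC
#' `sigma_u^2 / (sigma_u^2 + pi^2/3)` from a random-intercept logistic model.
#'
#' @param data Analysis data frame with `school_id`.
#' @param outcome Outcome column.
#' @param type `"continuous"` or `"binary"`.
#' @param adjusted Adjust for the covariates in `spec`.
#' @param spec An [analysis_spec()]; only its adjustment set is used.
#' @return ICC in `[0, 1)`.
#' @export
estimate_icc <- function(data, outcome, type = c("continuous", "binary"),
                         adjusted = FALSE, spec = analysis_spec()) {
  type <- match.arg(type)
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (length(unique(data$school_id)) < 2) {
    stop("need at least 2 schools", call. = FALSE)
  }
  spec$outcome <- outcome
  spec$crude <- !adjusted
  spec <- drop_constant_terms(spec, data)
  rhs <- if (adjusted) paste(c("arm", spec$baseline, spec$adjust),
                             collapse = " + ") else "1"
  f <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | school_id)"))
  if (type == "continuous") {
    fit <- lme4::lmer(f, data = data, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s_u <- vc$vcov[vc$grp == "school_id"]
    s_e <- vc$vcov[vc$grp == "Residual"]
    s_u / (s_u + s_e)
  } else {
    fit <- suppressMessages(lme4::glmer(f, data = data,
                                        family = stats::binomial(),
                                        nAGQ = 1))
    s_u <- as.data.frame(lme4::VarCorr(fit))$vcov[1]
    s_u / (s_u + pi^2 / 3)
  }
}

#' One-way ANOVA estimator of the ICC
#'
#' The classical analysis-of-variance estimator
#' `(MSB - MSW) / (MSB + (n0 - 1) MSW)` with `n0` the standard correction for
#' unequal cluster sizes. Reported alongside model-based crude ICCs because
#' it is the estimator most useful to planners of future cluster trials; also
#' serves as an independent oracle in simulation checks.
#'
#' @param y Numeric outcome vector.
#' @param cluster Cluster identifier vector.
#' @return ICC estimate (can be slightly negative in small samples).
#' @export
anova_icc <- function(y, cluster) {
  ok <- !is.na(y) & !is.na(cluster)
  y <- y[ok]
  cluster <- factor(cluster[ok])
  k <- nlevels(cluster)
  n <- length(y)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)
  nj <- tabulate(cluster)
  ybar_j <- tapply(y, cluster, mean)
  ssb <- sum(nj * (ybar_j - mean(y))^2)
  ssw <- sum((y - ybar_j[cluster])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  n0 <- (n - sum(nj^2) / n) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Pool estimates across multiply imputed datasets by Rubin's rules
#'
#' Pooled point estimate `Qbar`, within-imputation variance `W`,
#' between-imputation variance `B`, total variance `T = W + (1 + 1/m) B`,
#' and CI / p-value using the standard degrees-of-freedom formula
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`. Odds ratios must be pooled on
#' the log scale (`log = TRUE` exponentiates the reported estimate and CI).
#'
#' @param estimates Per-imputation point estimates (log-OR scale for odds
#'   ratios).
#' @param ses Per-imputation standard errors.
#' @param log Report `exp()` of the pooled estimate and CI.
#' @param conf_level Confidence level.
#' @return Object of class `"pooled_estimate"` with `estimate`, `se`, `ci`,
#'   `p`, `df`, `m`, `within`, `between`, `total`.
#' @export
pool_rubin <- function(estimates, ses, log = FALSE, conf_level = 0.95) {
  if (length(estimates) != length(ses)) {
    stop("estimates and ses must have equal length", call. = FALSE)
  }
  m <- length(estimates)
  if (m < 2) stop("need at least 2 imputations", call. = FALSE)
  qbar <- mean(estimates)
  W <- mean(ses^2)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  se <- sqrt(Tv)
  df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  ci <- qbar + c(-1, 1) * tq * se
  p <- 2 * stats::pt(-abs(qbar / se), df)
  out <- list(estimate = if (log) exp(qbar) else qbar,
              pooled_q = qbar, se = se,
              ci = if (log) exp(ci) else ci, p = p, df = df, m = m,
              within = W, between = B, total = Tv)
  structure(out, class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled over m = %d: %.4f (95%% CI %.4f to %.4f), p = %.4g\n",
              x$m, x$estimate, x$ci[1], x$ci[2], x$p))
  cat(sprintf("  W = %.4g, B = %.4g, T = %.4g, df = %.1f\n", x$within,
              x$between, x$total, x$df))
  invisible(x)
}

#' Test a pre-specified moderator by arm-by-moderator interaction
#'
#' Fits the primary GEE model with an `arm:moderator` interaction and tests
#' the interaction terms jointly by a robust Wald test; reports subgroup
#' intervention effects with 95% CIs. Moderator results are exploratory.
#'
#' @param data Analysis data frame.
#' @param moderator Moderator column name (factor or dichotomised variable).
#' @param spec An [analysis_spec()] for the binary primary outcome.
#' @return List with `interaction_p`, `wald`, `df` and `subgroups`
#'   (data frame: level, n, OR, CI bounds).
#' @export
test_moderation <- function(data, moderator, spec = analysis_spec()) {
  data <- data[!is.na(data[[spec$outcome]]) & !is.na(data[[moderator]]), ,
               drop = FALSE]
  mod <- factor(data[[moderator]])
  if (nlevels(droplevels(mod)) < 2) {
    stop("moderator has fewer than 2 observed levels", call. = FALSE)
  }
  data[[moderator]] <- droplevels(mod)
  spec2 <- drop_constant_terms(spec, data)
  spec2$adjust <- setdiff(spec2$adjust, moderator)
  f <- build_formula(spec2, extra = paste0("arm * ", moderator))
  fit <- gee_logit(f, data, cluster = "school_id")
  int_ix <- grep(paste0("^arm:"), names(fit$coefficients))
  if (!length(int_ix)) stop("no interaction terms estimable", call. = FALSE)
  b <- fit$coefficients[int_ix]
  V <- fit$robust.vcov[int_ix, int_ix, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  p_int <- stats::pchisq(W, df = length(b), lower.tail = FALSE)
  subgroups <- lapply(levels(data[[moderator]]), function(l) {
    d <- data[data[[moderator]] == l, , drop = FALSE]
    est <- tryCatch({
      sp <- drop_constant_terms(spec2, d)
      g <- gee_logit(build_formula(sp), d, cluster = "school_id")
      bb <- g$coefficients[["arm"]]
      ss <- sqrt(g$robust.vcov["arm", "arm"])
      c(or = exp(bb), lo = exp(bb - 1.96 * ss), hi = exp(bb + 1.96 * ss),
        n = g$n)
    }, error = function(e) c(or = NA, lo = NA, hi = NA, n = nrow(d)))
    data.frame(level = l, n = est[["n"]], or = est[["or"]],
               ci_lower = est[["lo"]], ci_upper = est[["hi"]])
  })
  list(moderator = moderator, wald = W, df = length(b), interaction_p = p_int,
       subgroups = do.call(rbind, subgroups))
}

#' Restrict to participants followed up within the pre-specified window
#'
#' The 12-month assessment window extends to +12 weeks after the due date;
#' the sensitivity analysis retains only children assessed within it.
#'
#' @param data Analysis data frame with the follow-up delay column.
#' @param weeks_col Column holding weeks late (NA = not assessed).
#' @param window Window width in weeks (default 12).
#' @return Filtered data frame.
#' @export
sensitivity_within_window <- function(data, weeks_col = "fu_weeks_late",
                                      window = 12) {
  if (!weeks_col %in% names(data)) {
    stop("follow-up timing column not found", call. = FALSE)
  }
  data[!is.na(data[[weeks_col]]) & data[[weeks_col]] <= window, ,
       drop = FALSE]
}
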