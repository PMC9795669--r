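# Bayesian multilevel path analysis for mediation: a random-intercept linear
# model for the mediator, random-intercept logistic models for the outcome
# (with and without the mediator), posterior indirect effect a*b and
# proportion mediated, pooled across imputed datasets by concatenating
# posterior draws. Models are fitted by Gibbs sampling (JAGS) with weakly
# informative priors that are recorded on the returned objects.

#' Mediation analysis specification
#'
#' @param mediator Mediator column name (a continuous 12-week measure, e.g.
#'   the scored PAS, STSC-approach, GAD-7, POS, PSOC-SE, CAMP, CQ-P or RULES
#'   total).
#' @param baseline Baseline measure of the mediator (`NULL` when the
#'   instrument has no baseline assessment).
#' @param covariates Pre-specified adjustment set Z.
#' @param prior_scale Prior SD for regression coefficients on standardised
#'   predictors (normal, mean 0); random-effect and residual scales get
#'   half-normal priors with the same scale.
#' @param chains,iter,warmup MCMC controls per imputation (post-warmup
#'   `iter` draws per chain).
#' @param seed Integer seed.
#' @return Object of class `"mediation_spec"`.
#' @export
mediation_spec <- function(mediator, baseline = NULL,
                           covariates = c("fsm_stratum", "cluster_size",
                                          "gender", "year_group", "batch",
                                          "imd_decile"),
                           prior_scale = 2.5, chains = 4, iter = 1000,
                           warmup = 500, seed = 1) {
  structure(list(mediator = mediator, baseline = baseline,
                 covariates = covariates, prior_scale = prior_scale,
                 chains = chains, iter = iter, warmup = warmup, seed = seed),
            class = "mediation_spec")
}

.jags_linear <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(inprod(X[i, ], beta) + u[school[i]], tau_e)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta[k]) }
  sigma_e ~ dnorm(0, prec_scale) T(0, )
  sigma_u ~ dnorm(0, prec_scale) T(0, )
  tau_e <- pow(sigma_e, -2)
  tau_u <- pow(sigma_u, -2)
}"

.jags_logistic <- "
model {
  for (i in 1:N) {
    y[i] ~ dbern(ilogit(inprod(X[i, ], beta) + u[school[i]]))
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta[k]) }
  sigma_u ~ dnorm(0, prec_scale) T(0, )
  tau_u <- pow(sigma_u, -2)
}"

# single-cluster variants: with one school a random intercept is not
# identified, so the cluster term is dropped (used for oracle validation on
# unclustered toy data)
.jags_linear_flat <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(inprod(X[i, ], beta), tau_e) }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta[k]) }
  sigma_e ~ dnorm(0, prec_scale) T(0, )
  tau_e <- pow(sigma_e, -2)
}"

.jags_logistic_flat <- "
model {
  for (i in 1:N) { y[i] ~ dbern(ilogit(inprod(X[i, ], beta))) }
  for (k in 1:P) { beta[k] ~ dnorm(0, prec_beta[k]) }
}"

# Build a design matrix with standardised continuous covariates (binary and
# dummy columns are left on their natural scale so coefficient priors are
# weakly informative for all of them).
mediation_design <- function(data, terms) {
  if (!length(terms)) return(matrix(1, nrow(data), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, data)
  for (k in seq_len(ncol(X))[-1]) {
    v <- X[, k]
    if (length(unique(v)) > 2) {
      X[, k] <- (v - mean(v)) / stats::sd(v)
    }
  }
  X
}

# Fit one JAGS model and return a draws matrix plus split-Rhat / ESS
# diagnostics for the monitored coefficients.
fit_jags <- function(model_string, y, X, school, spec, seed,
                     monitor = "beta") {
  J <- length(unique(school))
  school_i <- as.integer(factor(school))
  prec_beta <- rep(1 / spec$prior_scale^2, ncol(X))
  prec_beta[1] <- 1 / 100  # diffuse intercept
  if (J < 2) {
    model_string <- if (identical(model_string, .jags_linear)) {
      .jags_linear_flat
    } else .jags_logistic_flat
    dat <- list(y = y, X = X, N = length(y), P = ncol(X),
                prec_beta = prec_beta,
                prec_scale = 1 / spec$prior_scale^2)
  } else {
    dat <- list(y = y, X = X, school = school_i, N = length(y), J = J,
                P = ncol(X), prec_beta = prec_beta,
                prec_scale = 1 / spec$prior_scale^2)
  }
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, ch))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = max(200, spec$warmup %/% 2),
                          quiet = TRUE)
  stats::update(jm, spec$warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitor, n.iter = spec$iter,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  bcols <- grep("^beta\\[", colnames(draws))
  colnames(draws)[bcols] <- colnames(X)
  diag <- list(rhat = split_rhat(samp),
               ess = tryCatch(min(coda::effectiveSize(samp)),
                              error = function(e) NA_real_))
  list(draws = draws, diag = diag)
}

#' Split-chain R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, returned as the maximum over monitored parameters.
#'
#' @param samples A `coda::mcmc.list`.
#' @return Maximum split R-hat.
#' @export
split_rhat <- function(samples) {
  mats <- lapply(samples, as.matrix)
  half <- floor(nrow(mats[[1]]) / 2)
  halves <- list()
  for (m in mats) {
    halves[[length(halves) + 1]] <- m[seq_len(half), , drop = FALSE]
    halves[[length(halves) + 1]] <- m[half + seq_len(half), , drop = FALSE]
  }
  rhats <- vapply(seq_len(ncol(mats[[1]])), function(k) {
    ch <- vapply(halves, function(h) c(mean(h[, k]), stats::var(h[, k])),
                 numeric(2))
    W <- mean(ch[2, ])
    B <- half * stats::var(ch[1, ])
    if (W < 1e-12) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 1)
  max(rhats)
}

check_diag <- function(diag, what, strict) {
  if (is.finite(diag$rhat) && diag$rhat > 1.01) {
    msg <- sprintf("%s: split R-hat %.3f exceeds 1.01", what, diag$rhat)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
}

#' Posterior draws of the arm-to-mediator path (a)
#'
#' Random-intercept linear regression of the 12-week mediator on arm and the
#' covariate set Z, fitted by MCMC under weakly informative priors
#' (normal(0, `prior_scale`) coefficients on standardised predictors,
#' half-normal scales). The prior specification is recorded on the result.
#'
#' @param data Analysis data frame (one imputed dataset or complete cases).
#' @param spec A [mediation_spec()].
#' @param strict Error (rather than warn) when split R-hat exceeds 1.01.
#' @return List with `a` (draws), `draws` (all coefficients), `diag`,
#'   `priors`.
#' @export
sample_mediator_model <- function(data, spec, strict = FALSE) {
  terms <- c("arm", spec$baseline, intersect(spec$covariates, names(data)))
  d <- data[stats::complete.cases(data[, c(spec$mediator, terms)]), ]
  X <- mediation_design(d, terms)
  res <- fit_jags(.jags_linear, as.numeric(d[[spec$mediator]]), X,
                  d$school_id, spec, spec$seed)
  check_diag(res$diag, "mediator model", strict)
  list(a = res$draws[, "arm"], draws = res$draws, diag = res$diag,
       priors = prior_description(spec))
}

#' Posterior draws of the mediator and direct paths (b, c')
#'
#' Random-intercept logistic regression of the binary outcome on the
#' mediator, arm and Z.
#'
#' @inheritParams sample_mediator_model
#' @param outcome Binary outcome column.
#' @return List with `b`, `c_prime`, `draws`, `diag`, `priors`.
#' @export
sample_outcome_model <- function(data, spec, outcome = "anxiety_disorder_12m",
                                 strict = FALSE) {
  terms <- c("arm", spec$mediator, spec$baseline,
             intersect(spec$covariates, names(data)))
  d <- data[stats::complete.cases(data[, c(outcome, terms)]), ]
  y <- as.integer(d[[outcome]])
  if (length(unique(y)) < 2) stop("outcome constant", call. = FALSE)
  X <- mediation_design(d, terms)
  # the mediator column is continuous and standardised by mediation_design;
  # rescale its draws back to the mediator's natural units
  sd_m <- stats::sd(d[[spec$mediator]])
  res <- fit_jags(.jags_logistic, y, X, d$school_id, spec,
                  derive_seed(spec$seed, 101))
  check_diag(res$diag, "outcome model", strict)
  list(b = res$draws[, spec$mediator] / sd_m,
       c_prime = res$draws[, "arm"], draws = res$draws, diag = res$diag,
       priors = prior_description(spec))
}

#' Posterior draws of the total arm effect (c)
#'
#' Random-intercept logistic regression of the outcome on arm and Z (the
#' cluster-specific analogue of the intention-to-treat effect).
#'
#' @inheritParams sample_outcome_model
#' @return List with `c` (draws), `draws`, `diag`, `priors`.
#' @export
sample_total_model <- function(data, spec, outcome = "anxiety_disorder_12m",
                               strict = FALSE) {
  terms <- c("arm", spec$baseline, intersect(spec$covariates, names(data)))
  d <- data[stats::complete.cases(data[, c(outcome, terms)]), ]
  y <- as.integer(d[[outcome]])
  if (length(unique(y)) < 2) stop("outcome constant", call. = FALSE)
  X <- mediation_design(d, terms)
  res <- fit_jags(.jags_logistic, y, X, d$school_id, spec,
                  derive_seed(spec$seed, 202))
  check_diag(res$diag, "total model", strict)
  list(c = res$draws[, "arm"], draws = res$draws, diag = res$diag,
       priors = prior_description(spec))
}

prior_description <- function(spec) {
  sprintf(paste0("coefficients ~ normal(0, %.2f) on standardised predictors",
                 " (intercept normal(0, 10)); scales ~ half-normal(0, %.2f)"),
          spec$prior_scale, spec$prior_scale)
}

#' Indirect effect and proportion mediated from path draws
#'
#' Multiplies aligned posterior samples of `a` and `b` iteration by
#' iteration to obtain the posterior of the indirect effect `ab`, and forms
#' the proportion mediated `ab / (ab + c')` the same way. When `ab` and `c'`
#' draws have opposing signs the proportion can fall outside `[0, 1]`; it is
#' reported unmodified with a warning, never truncated.
#'
#' @param a,b,c_prime Aligned posterior draw vectors (equal length).
#' @return List of class `"mediation_draws"` with draw vectors `ab`,
#'   `prop_mediated` and a `summary()`-style list of posterior means and 95%
#'   credible intervals (2.5% / 97.5% percentiles).
#' @export
indirect_effect <- function(a, b, c_prime) {
  if (length(a) != length(b) || length(a) != length(c_prime)) {
    stop("draw vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(a, b, c_prime)))) {
    stop("non-finite posterior draws", call. = FALSE)
  }
  ab <- a * b
  prop <- ab / (ab + c_prime)
  frac_outside <- mean(prop < 0 | prop > 1, na.rm = TRUE)
  if (is.finite(frac_outside) && frac_outside > 0.5) {
    warning(paste("indirect and direct effects oppose in sign for most",
                  "draws; the proportion mediated is reported as-is and",
                  "falls outside [0, 1]"), call. = FALSE)
  }
  structure(list(ab = ab, prop_mediated = prop,
                 summary = list(
                   ab_mean = mean(ab),
                   ab_cri = stats::quantile(ab, c(0.025, 0.975), names = FALSE),
                   prop_mean = mean(prop),
                   prop_cri = stats::quantile(prop, c(0.025, 0.975),
                                              names = FALSE))),
            class = "mediation_draws")
}

#' Pool mediation posteriors across imputed datasets
#'
#' Posterior draw sets from each imputed dataset are simply concatenated;
#' the pooled posterior mean and 95% credible interval are computed on the
#' combined draws.
#'
#' @param draw_sets List of `"mediation_draws"` objects (one per imputation).
#' @return A `"mediation_draws"` object over the concatenated draws.
#' @export
pool_across_imputations <- function(draw_sets) {
  if (!length(draw_sets)) stop("no draw sets supplied", call. = FALSE)
  ab <- unlist(lapply(draw_sets, `[[`, "ab"))
  prop <- unlist(lapply(draw_sets, `[[`, "prop_mediated"))
  structure(list(ab = ab, prop_mediated = prop,
                 summary = list(
                   ab_mean = mean(ab),
                   ab_cri = stats::quantile(ab, c(0.025, 0.975), names = FALSE),
                   prop_mean = mean(prop),
                   prop_cri = stats::quantile(prop, c(0.025, 0.975),
                                              names = FALSE))),
            class = "mediation_draws")
}

#' @export
print.mediation_draws <- function(x, ...) {
  s <- x$summary
  cat(sprintf("indirect effect ab: %.4f (95%% CrI %.4f to %.4f)\n",
              s$ab_mean, s$ab_cri[1], s$ab_cri[2]))
  cat(sprintf("proportion mediated: %.4f (95%% CrI %.4f to %.4f)\n",
              s$prop_mean, s$prop_cri[1], s$prop_cri[2]))
  invisible(x)
}

#' End-to-end mediation analysis for one mediator
#'
#' Fits the mediator and outcome models on each supplied dataset (a list of
#' imputed datasets or a single data frame), forms the per-imputation
#' indirect-effect posteriors and pools them by concatenation.
#'
#' @param datasets A data frame or list of data frames.
#' @param spec A [mediation_spec()].
#' @param outcome Binary outcome column.
#' @param strict Convergence handling passed to the samplers.
#' @return Pooled `"mediation_draws"` with attribute `"per_imputation"`.
#' @export
mediate <- function(datasets, spec, outcome = "anxiety_disorder_12m",
                    strict = FALSE) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  per <- lapply(seq_along(datasets), function(i) {
    sp <- spec
    sp$seed <- derive_seed(spec$seed, 1000 + i)
    med <- sample_mediator_model(datasets[[i]], sp, strict = strict)
    out <- sample_outcome_model(datasets[[i]], sp, outcome = outcome,
                                strict = strict)
    k <- min(length(med$a), length(out$b))
    indirect_effect(med$a[seq_len(k)], out$b[seq_len(k)],
                    out$c_prime[seq_len(k)])
  })
  pooled <- pool_across_imputations(per)
  attr(pooled, "per_imputation") <- per
  pooled
}
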