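# Multilevel joint-model multiple imputation: a data-augmentation Gibbs
# sampler for a multivariate normal model with school-level random
# intercepts, applied jointly to all (possibly transformed) analysis
# variables, with the stated deterministic rounding rules for binary and
# categorical imputations.
#
# Model: y_i = mu + u_{j(i)} + e_i,  u_j ~ N_p(0, Psi),  e_i ~ N_p(0, Sigma),
# with inverse-Wishart priors on Sigma and Psi and a flat prior on mu.
# Fully observed variables (arm, design covariates, the auxiliary
# modules-completed count) are columns of y and condition the draws of the
# missing cells; categorical variables enter as k-1 dummies.

#' Imputation model specification
#'
#' @param variables Character vector of variable names to include in the
#'   joint model: all outcomes at all timepoints, allocated arm, the
#'   randomisation-balancing variables, adjustment covariates, any feasible
#'   moderators/mediators, and the auxiliary intervention-usage variable.
#' @param binary Subset of `variables` that are binary; continuous draws are
#'   rounded to 0 if `< 0.5` and to 1 otherwise.
#' @param categorical Named list mapping a variable name to its level labels
#'   (k levels become k-1 dummies; the reference dummy is reconstructed as
#'   `1 - sum(m_i)` and the level with the largest value is assigned).
#' @param transform Named character vector of per-variable transformations
#'   applied before fitting and inverted after drawing (currently `"log"`
#'   and `"log1p"`).
#' @param auxiliary Name of the auxiliary variable (module completion count;
#'   must be 0 for all control-arm records).
#' @param m Number of imputed datasets (default 50).
#' @param burnin,thin MCMC burn-in and between-draw thinning.
#' @param seed Integer seed.
#' @return Object of class `"imputation_spec"`.
#' @export
imputation_spec <- function(variables, binary = character(0),
                            categorical = list(),
                            transform = character(0),
                            auxiliary = "modules_completed",
                            m = 50, burnin = 1000, thin = 100, seed = 1) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  stopifnot(all(binary %in% variables), all(names(categorical) %in% variables))
  structure(list(variables = variables, binary = binary,
                 categorical = categorical, transform = transform,
                 auxiliary = auxiliary, m = m, burnin = burnin, thin = thin,
                 seed = seed),
            class = "imputation_spec")
}

apply_transform <- function(x, how) {
  switch(how, log = log(x), log1p = log1p(x),
         stop("unknown transformation: ", how, call. = FALSE))
}
invert_transform <- function(x, how) {
  switch(how, log = exp(x), log1p = expm1(x))
}

# Build the numeric joint-model matrix from the data frame: transforms
# applied, categorical variables expanded into k-1 dummies.
build_joint_matrix <- function(data, spec) {
  cols <- list()
  for (v in spec$variables) {
    if (!v %in% names(data)) stop("variable not in data: ", v, call. = FALSE)
    if (all(is.na(data[[v]]))) {
      stop("variable has no observed values: ", v, call. = FALSE)
    }
    if (v %in% names(spec$categorical)) {
      lev <- spec$categorical[[v]]
      f <- factor(data[[v]], levels = lev)
      for (l in lev[-length(lev)]) {
        cols[[paste0(v, "..", l)]] <- as.numeric(f == l)
      }
    } else {
      x <- as.numeric(data[[v]])
      if (v %in% names(spec$transform)) {
        x <- apply_transform(x, spec$transform[[v]])
      }
      cols[[v]] <- x
    }
  }
  do.call(cbind, cols)
}

#' Fit the joint multilevel imputation model
#'
#' Initialises the data-augmentation Gibbs sampler for the multivariate
#' random-intercept normal model over the specified variable vector. Checks
#' that the auxiliary variable is zero for all control-arm records when both
#' columns are present.
#'
#' @param data Child-level data frame with a `school_id` column.
#' @param spec An [imputation_spec()].
#' @return Object of class `"joint_model_state"` (the initialised sampler).
#' @export
fit_joint_model <- function(data, spec) {
  stopifnot(inherits(spec, "imputation_spec"))
  if (length(unique(data$school_id)) < 2) {
    stop("need at least 2 schools", call. = FALSE)
  }
  if (spec$auxiliary %in% spec$variables && "arm" %in% names(data)) {
    aux <- data[[spec$auxiliary]][data$arm == 0]
    if (any(aux != 0, na.rm = TRUE)) {
      stop("auxiliary module count must be zero in the control arm",
           call. = FALSE)
    }
  }
  Y <- build_joint_matrix(data, spec)
  p <- ncol(Y)
  n <- nrow(Y)
  school <- factor(data$school_id)
  J <- nlevels(school)
  miss <- is.na(Y)
  # column-mean initialisation of missing cells
  mu0 <- colMeans(Y, na.rm = TRUE)
  for (k in seq_len(p)) Y[miss[, k], k] <- mu0[k]
  v0 <- apply(Y, 2, stats::var)
  v0[v0 < 1e-8] <- 1e-8
  # group rows by missingness pattern once; the sampler reuses the grouping
  pat <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  patterns <- lapply(setdiff(unique(pat), ""), function(pp) {
    mis <- as.integer(strsplit(pp, ",")[[1]])
    list(rows = which(pat == pp), mis = mis,
         obs = setdiff(seq_len(p), mis))
  })
  state <- list(
    patterns = patterns,
    Y = Y, miss = miss, school = school, J = J, n = n, p = p,
    mu = mu0,
    Sigma = diag(v0, p), Psi = diag(v0 / 10, p),
    U = matrix(0, J, p),
    prior = list(nu_e = p + 2, S_e = diag(v0, p),
                 nu_u = p + 2, S_u = diag(v0 / 10, p)),
    spec = spec, data = data,
    mu_trace = list()
  )
  class(state) <- "joint_model_state"
  state
}

# One Gibbs sweep: missing cells | (mu, U, Sigma); U | rest; mu | rest;
# Sigma, Psi | rest.
gibbs_step <- function(st) {
  p <- st$p
  Y <- st$Y
  center <- st$mu[col(Y)] + st$U[st$school, , drop = FALSE]
  # 1. missing data given everything else, by missingness pattern
  for (pg in st$patterns) {
    rows <- pg$rows
    mis <- pg$mis
    obs <- pg$obs
    S_oo <- st$Sigma[obs, obs, drop = FALSE]
    S_mo <- st$Sigma[mis, obs, drop = FALSE]
    S_mm <- st$Sigma[mis, mis, drop = FALSE]
    if (length(obs)) {
      K <- S_mo %*% solve(S_oo)
      cond_S <- S_mm - K %*% t(S_mo)
      resid_o <- Y[rows, obs, drop = FALSE] - center[rows, obs, drop = FALSE]
      cond_mu <- center[rows, mis, drop = FALSE] + resid_o %*% t(K)
    } else {
      cond_S <- S_mm
      cond_mu <- center[rows, mis, drop = FALSE]
    }
    cond_S <- (cond_S + t(cond_S)) / 2
    draw <- rmvnorm_chol(length(rows), rep(0, length(mis)), cond_S) + cond_mu
    Y[rows, mis] <- draw
  }
  st$Y <- Y
  # 2. random effects per school
  Sig_inv <- solve(st$Sigma)
  Psi_inv <- solve(st$Psi)
  resid <- sweep(Y, 2, st$mu)
  for (j in seq_len(st$J)) {
    rows <- which(as.integer(st$school) == j)
    nj <- length(rows)
    prec <- nj * Sig_inv + Psi_inv
    V <- solve(prec)
    mean_j <- V %*% (Sig_inv %*% colSums(resid[rows, , drop = FALSE]))
    st$U[j, ] <- drop(rmvnorm_chol(1, drop(mean_j), (V + t(V)) / 2))
  }
  # 3. grand mean (flat prior)
  dev <- Y - st$U[st$school, , drop = FALSE]
  st$mu <- drop(rmvnorm_chol(1, colMeans(dev), st$Sigma / st$n))
  # 4. covariances (inverse-Wishart)
  E <- dev - matrix(st$mu, st$n, p, byrow = TRUE)
  st$Sigma <- riwish(st$prior$nu_e + st$n, st$prior$S_e + crossprod(E))
  st$Psi <- riwish(st$prior$nu_u + st$J, st$prior$S_u + crossprod(st$U))
  st$mu_trace[[length(st$mu_trace) + 1]] <- st$mu
  st
}

# Reconstruct a completed data frame from the current augmented Y matrix:
# observed cells are restored bitwise from the input data; only missing
# cells receive imputed values (back-transformed, with Allison rounding for
# binary variables and argmax reconstruction for categorical ones).
reconstruct_dataset <- function(st) {
  spec <- st$spec
  out <- st$data
  Y <- st$Y
  cn <- colnames(Y)
  for (v in spec$variables) {
    if (v %in% names(spec$categorical)) {
      lev <- spec$categorical[[v]]
      dcols <- match(paste0(v, "..", lev[-length(lev)]), cn)
      miss_rows <- which(is.na(out[[v]]))
      for (r in miss_rows) {
        out[[v]][r] <- lev[assign_categorical(Y[r, dcols])]
      }
    } else {
      k <- match(v, cn)
      x <- Y[, k]
      if (v %in% names(spec$transform)) {
        x <- invert_transform(x, spec$transform[[v]])
      }
      miss_rows <- is.na(out[[v]])
      if (v %in% spec$binary) x <- round_binary(x)
      # continuous draws outside the plausible range are retained unrounded
      out[[v]][miss_rows] <- x[miss_rows]
    }
  }
  out
}

#' Draw multiply imputed datasets
#'
#' Runs the Gibbs sampler for `burnin` sweeps and then retains `m` completed
#' datasets separated by `thin` sweeps. Observed cells are identical across
#' all datasets; binary cells are rounded by the 0.5 rule and categorical
#' cells reconstructed by the largest imputed category value. A basic
#' convergence summary (Geweke z-scores of the grand-mean chain) is attached.
#'
#' @param state A `"joint_model_state"` from [fit_joint_model()].
#' @param m Number of datasets (defaults to the spec's `m`).
#' @param seed Integer seed (defaults to the spec's seed).
#' @return Object of class `"imputed_sets"`: list with `datasets` (length
#'   `m`), `m`, `seed`, `spec`, `convergence`, and the retained draws of the
#'   between-school (`psi_draws`) and residual (`sigma_draws`) variance
#'   diagonals.
#' @export
draw_imputations <- function(state, m = NULL, seed = NULL) {
  stopifnot(inherits(state, "joint_model_state"))
  spec <- state$spec
  if (is.null(m)) m <- spec$m
  if (is.null(seed)) seed <- spec$seed
  st <- state
  datasets <- vector("list", m)
  psi_draws <- sigma_draws <- vector("list", m)
  with_seed(seed, {
    for (i in seq_len(spec$burnin)) st <- gibbs_step(st)
    for (d in seq_len(m)) {
      for (i in seq_len(spec$thin)) st <- gibbs_step(st)
      datasets[[d]] <- reconstruct_dataset(st)
      psi_draws[[d]] <- diag(st$Psi)
      sigma_draws[[d]] <- diag(st$Sigma)
    }
  })
  conv <- tryCatch({
    tr <- do.call(rbind, st$mu_trace)
    z <- coda::geweke.diag(coda::mcmc(tr))$z
    max(abs(z[is.finite(z)]))
  }, error = function(e) NA_real_)
  if (is.finite(conv) && conv > 5) {
    warning("imputation sampler may not have converged (|Geweke z| = ",
            round(conv, 1), ")")
  }
  psi <- do.call(rbind, psi_draws)
  sigma <- do.call(rbind, sigma_draws)
  colnames(psi) <- colnames(sigma) <- colnames(state$Y)
  structure(list(datasets = datasets, m = m, seed = seed, spec = spec,
                 convergence = conv, psi_draws = psi, sigma_draws = sigma),
            class = "imputed_sets")
}

#' @export
print.imputed_sets <- function(x, ...) {
  cat(sprintf("%d imputed datasets (%d rows, seed %d, max |Geweke z| %.2f)\n",
              x$m, nrow(x$datasets[[1]]), x$seed, x$convergence))
  invisible(x)
}

#' Round a continuous imputed value to binary
#'
#' Deterministic rule for binary variables: 0 if the imputed value is less
#' than 0.5, 1 if it is greater than or equal to 0.5.
#'
#' @param value Numeric vector of imputed values (must be finite).
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' round_binary(c(0.49, 0.5, -0.2))  # 0 1 0
round_binary <- function(value) {
  if (any(!is.finite(value))) stop("non-finite imputed value", call. = FALSE)
  as.integer(value >= 0.5)
}

#' Assign an imputed categorical variable from its dummy values
#'
#' With k levels imputed through k-1 dummy variables, the reference
#' category's value is `m_k = 1 - sum(m_i)`; the variable is assigned to the
#' category with the largest imputed value. Argmax ties are broken by the
#' lowest level index.
#'
#' @param dummy_values Numeric vector of the k-1 imputed dummy values.
#' @return Integer level index in `1..k`.
#' @export
#' @examples
#' assign_categorical(c(0.2, 0.3))  # reference = 0.5 -> level 3
assign_categorical <- function(dummy_values) {
  if (length(dummy_values) == 0) stop("empty dummy vector", call. = FALSE)
  vals <- c(dummy_values, 1 - sum(dummy_values))
  which.max(vals)  # which.max returns the first (lowest-index) maximum
}

#' Write imputed datasets as delimited text with a manifest
#'
#' @param sets An `"imputed_sets"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_imputed_sets <- function(sets, dir) {
  stopifnot(inherits(sets, "imputed_sets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in seq_len(sets$m)) {
    utils::write.csv(sets$datasets[[d]],
                     file.path(dir, sprintf("imp_%03d.csv", d)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(m = sets$m, seed = sets$seed,
                   variables = sets$spec$variables,
                   convergence_max_geweke_z = sets$convergence,
                   spec_digest = content_digest(sets$spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
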