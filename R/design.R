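# Trial design: class sampling, stratified blocked randomisation with
# pupil-count ordering, recruitment projection and variable-cluster-size
# power calculations.

#' Design assumptions for power and projection calculations
#'
#' Bundles the design quantities used by [projected_enrolment()],
#' [power_cluster_two_proportions()] and [required_schools()]. Defaults are
#' the reviewed recruitment assumptions: 27 pupils per class, 17% screening
#' participation, 37% of screened children enrolling, 80% follow-up, ICC 0.05
#' and cluster-size coefficient of variation 0.68, targeting a reduction in
#' 12-month anxiety-disorder prevalence from 0.50 to 0.35.
#'
#' @param p_control,p_intervention Outcome proportions under control and
#'   intervention.
#' @param alpha Two-sided significance level.
#' @param n_schools Number of schools (clusters), both arms combined.
#' @param classes_per_school Sampled classes per school (2 per year group).
#' @param pupils_per_class Mean pupils per sampled class.
#' @param participation_rate Proportion of invited children screened.
#' @param screen_positive_rate Proportion of screened children who screen
#'   positive and enrol.
#' @param followup_rate Proportion of enrolled children analysed at 12 months.
#' @param icc Intra-cluster (intra-school) correlation coefficient.
#' @param cv_cluster_size Coefficient of variation of enrolled cluster sizes
#'   (0 for a fixed cluster size).
#' @param enrolled,analysed Optional explicit counts overriding the funnel
#'   projection (used when matching a reported recruitment position).
#' @return An object of class `"power_spec"`.
#' @export
power_spec <- function(p_control = 0.50, p_intervention = 0.35, alpha = 0.05,
                       n_schools = 60, classes_per_school = 6,
                       pupils_per_class = 27, participation_rate = 0.17,
                       screen_positive_rate = 0.37, followup_rate = 0.80,
                       icc = 0.05, cv_cluster_size = 0.68,
                       enrolled = NULL, analysed = NULL) {
  for (p in list(p_control = p_control, p_intervention = p_intervention,
                 alpha = alpha, participation_rate = participation_rate,
                 screen_positive_rate = screen_positive_rate,
                 followup_rate = followup_rate)) {
    if (!is.numeric(p) || !is.finite(p) || p < 0 || p > 1) {
      stop("rates, proportions and alpha must lie in [0, 1]", call. = FALSE)
    }
  }
  assert_prob(icc, "icc", allow_one = FALSE)
  if (cv_cluster_size < 0) stop("cv_cluster_size must be >= 0", call. = FALSE)
  if (n_schools < 2) stop("need at least 2 schools", call. = FALSE)
  structure(list(p_control = p_control, p_intervention = p_intervention,
                 alpha = alpha, n_schools = n_schools,
                 classes_per_school = classes_per_school,
                 pupils_per_class = pupils_per_class,
                 participation_rate = participation_rate,
                 screen_positive_rate = screen_positive_rate,
                 followup_rate = followup_rate, icc = icc,
                 cv_cluster_size = cv_cluster_size,
                 enrolled = enrolled, analysed = analysed),
            class = "power_spec")
}

#' Projected recruitment funnel counts
#'
#' Projects invited, screened, enrolled and analysed counts from the design
#' assumptions, rounding half-up to the nearest integer at each stage (the
#' convention that reproduces the published projections: 60 schools give
#' 9720 invited, 1652 screened, 611 enrolled, 489 analysed; 86 schools give
#' 13932 / 2368 / 876 / 701).
#'
#' @param spec A [power_spec()].
#' @return Named numeric vector with elements `invited`, `screened`,
#'   `enrolled`, `analysed`.
#' @export
projected_enrolment <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  invited <- spec$n_schools * spec$classes_per_school * spec$pupils_per_class
  screened <- round_half_up(invited * spec$participation_rate)
  enrolled <- round_half_up(screened * spec$screen_positive_rate)
  analysed <- round_half_up(enrolled * spec$followup_rate)
  c(invited = invited, screened = screened, enrolled = enrolled,
    analysed = analysed)
}

#' Design effect for variable cluster sizes
#'
#' Variance inflation factor `1 + ((cv^2 + 1) * m_bar - 1) * icc`, which
#' reduces to the familiar `1 + (m_bar - 1) * icc` when all clusters have the
#' same size (`cv = 0`).
#'
#' @param mean_cluster_size Mean number of analysed/enrolled participants per
#'   cluster (`m_bar >= 1`).
#' @param icc Intra-cluster correlation in `[0, 1)`.
#' @param cv Coefficient of variation of cluster size (`>= 0`).
#' @return The design-effect multiplier.
#' @export
#' @examples
#' design_effect(18, 0.05, 0)      # 1.85
#' design_effect(10.3, 0.05, 0.68) # 1.7029...
design_effect <- function(mean_cluster_size, icc, cv = 0) {
  if (mean_cluster_size < 1) stop("mean cluster size must be >= 1", call. = FALSE)
  assert_prob(icc, "icc", allow_one = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  1 + ((cv^2 + 1) * mean_cluster_size - 1) * icc
}

#' Power for a two-arm cluster trial comparing two proportions
#'
#' Normal-approximation power for a two-sided test of `p_control` versus
#' `p_intervention`, allowing for clustering through the variable-cluster-size
#' design effect. The analysed sample size (enrolled x follow-up rate, split
#' 1:1) is divided by `design_effect(m_bar, icc, cv)` where `m_bar` is the
#' *recruited* (enrolled) mean cluster size — attrition reduces the effective
#' number analysed but the cluster-size distribution is set at recruitment.
#' This convention reproduces the published 74% (60 schools, 611 enrolled)
#' and 88% (86 schools, 876 enrolled / 701 analysed) figures.
#'
#' @param spec A [power_spec()].
#' @return Power as a proportion in (0, 1).
#' @export
power_cluster_two_proportions <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  invited <- spec$n_schools * spec$classes_per_school * spec$pupils_per_class
  enrolled <- if (!is.null(spec$enrolled)) spec$enrolled else {
    invited * spec$participation_rate * spec$screen_positive_rate
  }
  analysed <- if (!is.null(spec$analysed)) spec$analysed else {
    enrolled * spec$followup_rate
  }
  m_bar <- enrolled / spec$n_schools
  de <- design_effect(m_bar, spec$icc, spec$cv_cluster_size)
  n_eff <- (analysed / 2) / de
  if (n_eff < 2) stop("effective sample size per arm below 2", call. = FALSE)
  p1 <- spec$p_control
  p2 <- spec$p_intervention
  s <- sqrt(p1 * (1 - p1) + p2 * (1 - p2))
  z <- sqrt(n_eff) * abs(p1 - p2) / s - stats::qnorm(1 - spec$alpha / 2)
  stats::pnorm(z)
}

#' Smallest number of schools achieving a target power
#'
#' Scans school counts upwards under the funnel assumptions in `spec`
#' (explicit `enrolled`/`analysed` overrides are ignored: enrolment scales
#' with the number of schools).
#'
#' @param spec A [power_spec()].
#' @param target_power Target power in (0, 1).
#' @param max_schools Upper bound for the scan.
#' @return Integer school count.
#' @export
required_schools <- function(spec, target_power, max_schools = 1000) {
  stopifnot(inherits(spec, "power_spec"))
  assert_prob(target_power, "target_power")
  spec$enrolled <- NULL
  spec$analysed <- NULL
  for (n in 2:max_schools) {
    spec$n_schools <- n
    pw <- tryCatch(power_cluster_two_proportions(spec), error = function(e) 0)
    if (pw >= target_power) return(n)
  }
  stop(sprintf("target power %.2f not reachable with <= %d schools",
               target_power, max_schools), call. = FALSE)
}

#' Recruitment review summary
#'
#' Recomputes the observed recruitment-review quantities from stage counts:
#' mean enrolled cluster size, cluster-size coefficient of variation,
#' screening participation and enrolment-among-screened rates.
#'
#' @param n_schools Schools recruited so far.
#' @param screened Children screened.
#' @param enrolled Children enrolled.
#' @param sd_cluster_size Standard deviation of enrolled cluster sizes.
#' @param classes_per_school,pupils_per_class Invitation assumptions.
#' @return List with `invited`, `mean_cluster_size`, `cv_cluster_size`,
#'   `participation_rate`, `enrolment_rate`.
#' @export
#' @examples
#' r <- recruitment_review(35, 983, 360, 7.0)
#' round(r$mean_cluster_size, 1)  # 10.3
#' round(r$cv_cluster_size, 2)    # 0.68
recruitment_review <- function(n_schools, screened, enrolled, sd_cluster_size,
                               classes_per_school = 6, pupils_per_class = 27) {
  invited <- n_schools * classes_per_school * pupils_per_class
  mean_cs <- enrolled / n_schools
  list(invited = invited,
       mean_cluster_size = mean_cs,
       cv_cluster_size = sd_cluster_size / mean_cs,
       participation_rate = screened / invited,
       enrolment_rate = enrolled / screened)
}

#' Randomly sample two classes per year group
#'
#' Uniform sampling without replacement of exactly two classes from each year
#' group, reproducible from the seed.
#'
#' @param classes_by_year Named list (one element per year group) of class
#'   identifiers.
#' @param seed Integer seed.
#' @return Named list of two selected class identifiers per year group.
#' @export
sample_classes <- function(classes_by_year, seed) {
  stopifnot(is.list(classes_by_year))
  lens <- vapply(classes_by_year, length, 1L)
  if (any(lens < 2)) {
    stop("each year group needs at least 2 classes", call. = FALSE)
  }
  with_seed(seed, lapply(classes_by_year, function(cl) {
    if (length(cl) == 2) cl else sort(sample(cl, 2))
  }))
}

# Build a blocked 1:1 allocation sequence of at least n entries using blocks
# of the given sizes chosen uniformly at random, constrained so that block
# boundaries align with the stratum size whenever it is reachable (a block
# never overhangs the roster by more than the minimum needed); an even-sized
# stratum is therefore exactly balanced.
blocked_sequence <- function(n, block_sizes = c(2, 4)) {
  arms <- integer(0)
  blocks <- integer(0)
  while (length(arms) < n) {
    remaining <- n - length(arms)
    ok <- block_sizes[block_sizes <= remaining + 1]
    if (!length(ok)) ok <- min(block_sizes)
    b <- if (length(ok) == 1) ok else sample(ok, 1)
    arms <- c(arms, sample(rep(0:1, b / 2)))
    blocks <- c(blocks, b)
  }
  list(arms = arms, block_sizes = blocks)
}

#' Stratified blocked randomisation of schools
#'
#' Generates a 1:1 allocation list per deprivation stratum using randomly
#' mixed block sizes of two and four. Within each batch and stratum, schools
#' are ordered by the number of recruited pupils (descending; ties by school
#' id) before consuming entries from the stratum's list, so that arms stay
#' balanced on pupil numbers.
#'
#' @param schools Data frame with columns `school_id`, `batch`,
#'   `fsm_stratum` (factor/character/logical: above vs below the free-school-
#'   meals threshold) and `recruited_pupils`.
#' @param seed Integer seed.
#' @param block_sizes Permitted block sizes (balanced 1:1 within each block).
#' @return The input data frame with an added integer column `arm`
#'   (0 control / 1 intervention), ordered as allocated, with attributes
#'   `seed` and `block_sizes` (per-stratum block size sequences).
#' @export
generate_allocation <- function(schools, seed, block_sizes = c(2, 4)) {
  if (!is.data.frame(schools) || nrow(schools) == 0) {
    stop("empty school roster", call. = FALSE)
  }
  need <- c("school_id", "batch", "fsm_stratum", "recruited_pupils")
  if (!all(need %in% names(schools))) {
    stop("roster needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(block_sizes %% 2 != 0)) stop("block sizes must be even", call. = FALSE)
  with_seed(seed, {
    strata <- sort(unique(as.character(schools$fsm_stratum)))
    seqs <- list()
    for (s in strata) {
      n_s <- sum(schools$fsm_stratum == s)
      seqs[[s]] <- blocked_sequence(n_s, block_sizes)
    }
    used <- stats::setNames(rep(0L, length(strata)), strata)
    out <- schools[0, , drop = FALSE]
    out$arm <- integer(0)
    for (b in sort(unique(schools$batch))) {
      for (s in strata) {
        grp <- schools[schools$batch == b &
                         as.character(schools$fsm_stratum) == s, , drop = FALSE]
        if (nrow(grp) == 0) next
        grp <- grp[order(-grp$recruited_pupils, grp$school_id), , drop = FALSE]
        idx <- used[[s]] + seq_len(nrow(grp))
        grp$arm <- seqs[[s]]$arms[idx]
        used[[s]] <- used[[s]] + nrow(grp)
        out <- rbind(out, grp)
      }
    }
    attr(out, "seed") <- seed
    attr(out, "block_sizes") <- lapply(seqs, `[[`, "block_sizes")
    rownames(out) <- NULL
    out
  })
}
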