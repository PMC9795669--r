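# Questionnaire scoring: instrument definitions, totals with prorating,
# screening status, household tie-breaking and motivation categories.

# Internal registry of instrument definitions. Each entry mirrors the trial's
# published scoring and missing-item instructions:
#  - items are summed after reverse-scoring the listed items as
#    (item_min + item_max - value);
#  - a partially completed measure is prorated as mean(observed) * n_items
#    when at least `min_completed` items are observed, and treated as missing
#    when `missing_ge` or more items are missing
#    (min_completed + missing_ge = n_items + 1 for single-scale instruments);
#  - SDQ-E prorates each 5-item subscale (conduct, hyperactivity) separately,
#    requiring >= 3 completed items per subscale, before summing;
#  - CQ-P is scored as the first item only;
#  - at screening, PAS / STSC-A / GAD-7 allow no missing items.
.instruments <- list(
  pas = list(
    name = "pas", label = "Preschool Anxiety Scale (PAS)",
    n_items = 28L, item_min = 0, item_max = 4, reverse_items = integer(0),
    min_completed = 21L, missing_ge = 8L, screen_cutoff = 34,
    total_range = c(0, 112)
  ),
  stsc_a = list(
    name = "stsc_a", label = "STSC approach subscale (behavioural inhibition)",
    n_items = 7L, item_min = 1, item_max = 6, reverse_items = 3:6,
    min_completed = 6L, missing_ge = 2L, screen_cutoff = 30,
    total_range = c(7, 42)
  ),
  gad7 = list(
    name = "gad7", label = "Generalised Anxiety Disorder Scale (GAD-7)",
    n_items = 7L, item_min = 0, item_max = 3, reverse_items = integer(0),
    min_completed = 6L, missing_ge = 2L, screen_cutoff = 8,
    total_range = c(0, 21)
  ),
  calis_pv = list(
    name = "calis_pv", label = "Child Anxiety Life Interference Scale (preschool)",
    n_items = 18L, item_min = 0, item_max = 4, reverse_items = integer(0),
    min_completed = 14L, missing_ge = 5L, screen_cutoff = NULL,
    total_range = c(0, 72)
  ),
  sdq_e = list(
    name = "sdq_e", label = "SDQ externalising (conduct + hyperactivity)",
    n_items = 10L, item_min = 0, item_max = 2,
    # item positions within the 10 externalising items, ordered by their
    # full-questionnaire numbering (2,5,7,10,12,15,18,21,22,25); reversed
    # full-scale items 7, 21, 25 sit at positions 3, 8, 10
    reverse_items = c(3L, 8L, 10L),
    subscales = list(hyperactivity = c(1L, 4L, 6L, 8L, 10L),
                     conduct = c(2L, 3L, 5L, 7L, 9L)),
    min_completed_per_subscale = 3L,
    min_completed = NA_integer_, missing_ge = NA_integer_,
    screen_cutoff = NULL, total_range = c(0, 20)
  ),
  pos = list(
    name = "pos", label = "Parental Overprotection Scale (POS)",
    n_items = 19L, item_min = 0, item_max = 4, reverse_items = integer(0),
    min_completed = 15L, missing_ge = 5L, screen_cutoff = NULL,
    total_range = c(0, 76)
  ),
  psoc_se = list(
    name = "psoc_se", label = "PSOC self-efficacy subscale",
    n_items = 7L, item_min = 1, item_max = 6, reverse_items = integer(0),
    min_completed = 6L, missing_ge = 2L, screen_cutoff = NULL,
    total_range = c(7, 42)
  ),
  camp = list(
    name = "camp", label = "Child Avoidance Measure - Parent report (CAMP)",
    n_items = 8L, item_min = 0, item_max = 3, reverse_items = integer(0),
    min_completed = 6L, missing_ge = 3L, screen_cutoff = NULL,
    total_range = c(0, 24)
  ),
  rules = list(
    name = "rules", label = "Responses to Uncertainty and Low Environmental Structure",
    n_items = 17L, item_min = 1, item_max = 5, reverse_items = integer(0),
    min_completed = 13L, missing_ge = 5L, screen_cutoff = NULL,
    total_range = c(17, 85)
  ),
  cq_p = list(
    name = "cq_p", label = "Coping Questionnaire - Parent report (first item)",
    n_items = 3L, item_min = 1, item_max = 7, reverse_items = integer(0),
    first_item_only = TRUE,
    min_completed = 1L, missing_ge = NA_integer_, screen_cutoff = NULL,
    total_range = c(1, 7)
  ),
  motivation = list(
    name = "motivation", label = "Parent motivation questionnaire",
    n_items = 6L, item_min = 1, item_max = 5, reverse_items = 4L,
    min_completed = 5L, missing_ge = 2L, screen_cutoff = NULL,
    total_range = c(6, 30)
  )
)

#' Instrument specification lookup
#'
#' Returns the scoring specification for one questionnaire instrument:
#' item count and bounds, reverse-scored items, prorating and
#' treat-as-missing thresholds, screening cut-off (where defined) and the
#' valid total-score range.
#'
#' @param name Instrument key, one of `names(instrument_specs())`, e.g.
#'   `"pas"`, `"stsc_a"`, `"gad7"`, `"sdq_e"`, `"cq_p"`, `"motivation"`.
#' @return A list with the fields described above.
#' @export
#' @examples
#' instrument_spec("pas")$screen_cutoff  # 34
instrument_spec <- function(name) {
  name <- tolower(gsub("[^a-z0-9]+", "_", tolower(name)))
  spec <- .instruments[[name]]
  if (is.null(spec)) {
    stop(sprintf("unknown instrument '%s'; known: %s", name,
                 paste(names(.instruments), collapse = ", ")), call. = FALSE)
  }
  spec
}

#' All instrument specifications
#' @return Named list of instrument specifications.
#' @export
instrument_specs <- function() .instruments

# Reverse-score a response matrix in place (columns = items).
reverse_score <- function(mat, spec) {
  if (length(spec$reverse_items)) {
    ri <- spec$reverse_items
    mat[, ri] <- spec$item_min + spec$item_max - mat[, ri]
  }
  mat
}

#' Score a questionnaire instrument
#'
#' Computes the total score from item responses, applying reverse scoring and
#' the instrument's prorating / treat-as-missing rules. Prorated totals equal
#' `mean(observed items) * n_items` and are kept fractional (downstream models
#' are continuous; no rounding rule is defined for prorated totals). SDQ-E is
#' prorated per 5-item subscale before summing; CQ-P is scored as its first
#' item only.
#'
#' @param responses Numeric vector of length `n_items`, `NA` for missing
#'   items, or a matrix with one row per respondent.
#' @param spec Instrument specification from [instrument_spec()], or an
#'   instrument name.
#' @param screening If `TRUE`, apply the screening-stage rule: no missing
#'   items are allowed and no prorating is done (any gap gives a missing
#'   total).
#' @return For a vector input, a list of class `"scored_measure"` with
#'   `instrument`, `total` (may be `NA`), `prorated` flag and
#'   `n_items_completed`. For a matrix input, a data.frame with columns
#'   `total`, `prorated`, `n_items_completed`.
#' @export
#' @examples
#' score_measure(rep(1, 28), "pas")$total   # 28
#' x <- c(rep(2, 21), rep(NA, 7))
#' score_measure(x, "pas")$total            # prorated: 2 * 28 = 56
score_measure <- function(responses, spec, screening = FALSE) {
  if (is.character(spec)) spec <- instrument_spec(spec)
  vec_in <- is.null(dim(responses))
  mat <- if (vec_in) matrix(responses, nrow = 1) else as.matrix(responses)
  if (ncol(mat) != spec$n_items) {
    stop(sprintf("%s expects %d items, got %d", spec$name, spec$n_items,
                 ncol(mat)), call. = FALSE)
  }
  obs <- !is.na(mat)
  rng_bad <- mat < spec$item_min | mat > spec$item_max
  if (any(rng_bad & obs)) {
    stop(sprintf("item values outside [%g, %g] for %s", spec$item_min,
                 spec$item_max, spec$name), call. = FALSE)
  }
  mat <- reverse_score(mat, spec)
  n_comp <- rowSums(obs)
  n_miss <- spec$n_items - n_comp

  if (isTRUE(spec$first_item_only)) {
    total <- mat[, 1]
    prorated <- rep(FALSE, nrow(mat))
  } else if (!is.null(spec$subscales)) {
    sub_tot <- matrix(0, nrow(mat), length(spec$subscales))
    sub_ok <- matrix(TRUE, nrow(mat), length(spec$subscales))
    for (k in seq_along(spec$subscales)) {
      idx <- spec$subscales[[k]]
      sm <- mat[, idx, drop = FALSE]
      nc <- rowSums(!is.na(sm))
      sub_ok[, k] <- nc >= spec$min_completed_per_subscale
      sub_tot[, k] <- rowMeans(sm, na.rm = TRUE) * length(idx)
    }
    ok <- rowSums(sub_ok) == length(spec$subscales)
    total <- ifelse(ok, rowSums(sub_tot), NA_real_)
    prorated <- ok & n_miss > 0
  } else {
    full <- rowSums(mat)
    pro <- rowMeans(mat, na.rm = TRUE) * spec$n_items
    total <- ifelse(n_miss == 0, full,
                    ifelse(n_comp >= spec$min_completed, pro, NA_real_))
    prorated <- n_miss > 0 & n_comp >= spec$min_completed
  }
  if (screening) {
    total[n_miss > 0] <- NA_real_
    prorated <- prorated & FALSE
  }
  total[n_comp == 0] <- NA_real_
  if (vec_in) {
    structure(list(instrument = spec$name, total = total[1],
                   prorated = prorated[1], n_items_completed = n_comp[1]),
              class = "scored_measure")
  } else {
    data.frame(total = total, prorated = prorated, n_items_completed = n_comp)
  }
}

#' @export
print.scored_measure <- function(x, ...) {
  cat(sprintf("%s: total = %s%s (%d items completed)\n", x$instrument,
              format(x$total), if (isTRUE(x$prorated)) " (prorated)" else "",
              x$n_items_completed))
  invisible(x)
}

#' Screening status from the three risk instruments
#'
#' A child screens positive (is trial-eligible) if they meet at least one of:
#' child anxiety symptoms (PAS total >= 34), behavioural inhibition
#' (STSC-approach total >= 30) or parent anxiety (GAD-7 total >= 8).
#' Screening totals must be complete (no prorating at the screening stage).
#'
#' @param pas,stsc,gad7 Screening total scores (vectors are accepted).
#' @return Data frame with logical columns `child_anxiety`,
#'   `behavioural_inhibition`, `parent_anxiety` and `eligible`.
#' @export
screen_status <- function(pas, stsc, gad7) {
  if (any(is.na(pas)) || any(is.na(stsc)) || any(is.na(gad7))) {
    stop("screening scores must be complete (no missing items at screening)",
         call. = FALSE)
  }
  out <- data.frame(
    child_anxiety = pas >= .instruments$pas$screen_cutoff,
    behavioural_inhibition = stsc >= .instruments$stsc_a$screen_cutoff,
    parent_anxiety = gad7 >= .instruments$gad7$screen_cutoff
  )
  out$eligible <- out$child_anxiety | out$behavioural_inhibition |
    out$parent_anxiety
  out
}

#' Select the eligible child within a household
#'
#' At most one child per household may enrol. Among screen-positive children
#' sharing a household the child with the highest PAS score is selected; PAS
#' ties are broken by the highest STSC-approach score; residual ties are
#' broken deterministically by the lowest child identifier.
#'
#' @param candidates Data frame with columns `child_id`, `pas`, `stsc_a`
#'   (one row per screen-positive child in the household).
#' @return The selected row of `candidates` (single-row data frame).
#' @export
select_household_child <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    stop("empty candidate list", call. = FALSE)
  }
  need <- c("child_id", "pas", "stsc_a")
  if (!all(need %in% names(candidates))) {
    stop("candidates must have columns child_id, pas, stsc_a", call. = FALSE)
  }
  ord <- order(-candidates$pas, -candidates$stsc_a, candidates$child_id)
  candidates[ord[1], , drop = FALSE]
}

#' Categorise parent motivation
#'
#' Maps a motivation questionnaire total (range 6-30) to
#' `"ambivalent"` (6-18), `"partially motivated"` (19-23) or
#' `"motivated"` (24-30).
#'
#' @param total Numeric total score(s) in `[6, 30]`.
#' @return Factor with the three levels above.
#' @export
categorise_motivation <- function(total) {
  ok <- !is.na(total)
  if (any(total[ok] < 6 | total[ok] > 30)) {
    stop("motivation total out of range [6, 30]", call. = FALSE)
  }
  cut(total, breaks = c(6, 18, 23, 30), include.lowest = TRUE,
      labels = c("ambivalent", "partially motivated", "motivated"))
}

#' Score all instrument item tables of a trial dataset
#'
#' Applies [score_measure()] to every instrument measured at each timepoint of
#' a [generate_cohort()] trial table and returns the totals in long format.
#'
#' @param table A `trial_table` object.
#' @return Data frame with columns `child_id`, `timepoint`, `instrument`,
#'   `total`, `prorated`, `n_items_completed`.
#' @export
score_table <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  out <- list()
  for (tp in names(table$items)) {
    tab <- table$items[[tp]]
    if (is.null(tab) || nrow(tab) == 0) next
    for (inst in names(.instruments)) {
      cols <- grep(paste0("^", inst, "_i[0-9]+$"), names(tab), value = TRUE)
      if (!length(cols)) next
      sc <- score_measure(as.matrix(tab[, cols, drop = FALSE]),
                          .instruments[[inst]],
                          screening = identical(tp, "screening"))
      out[[length(out) + 1]] <- data.frame(
        child_id = tab$child_id, timepoint = tp, instrument = inst, sc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
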