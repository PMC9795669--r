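# CONSORT-style flow accounting, baseline characteristic tables,
# missingness summaries and eligible participant vs non-participant
# screening comparisons.

fmt_pct <- function(x) {
  # one decimal place, half-up
  sprintf("%.1f", floor(x * 1000 + 0.5) / 10)
}

#' CONSORT-style flow report
#'
#' Funnel counts by stage (overall and by arm from randomisation onwards),
#' children assessed at each follow-up timepoint, losses between consecutive
#' timepoints, and the mean / SD of enrolled cluster sizes by arm at each
#' timepoint.
#'
#' @param table A `trial_table`.
#' @return List of class `"flow_report"` with `funnel`, `assessed`,
#'   `lost_between`, `cluster_sizes`.
#' @export
build_flow <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master
  if (any(m$enrolled & !m$screened)) {
    stop("inconsistent stage flags: enrolled but not screened", call. = FALSE)
  }
  funnel <- funnel_counts(table)
  tps <- intersect(c("t0", "t1", "t2", "t3"), names(table$items))
  assessed <- lapply(tps, function(tp) {
    tab <- table$items[[tp]]
    item_cols <- setdiff(names(tab), "child_id")
    ids <- tab$child_id[rowSums(!is.na(tab[, item_cols, drop = FALSE])) > 0]
    arm <- m$arm[match(ids, m$child_id)]
    data.frame(timepoint = tp, overall = length(ids),
               control = sum(arm == 0, na.rm = TRUE),
               intervention = sum(arm == 1, na.rm = TRUE))
  })
  assessed <- do.call(rbind, assessed)
  lost <- data.frame(
    interval = paste(utils::head(assessed$timepoint, -1),
                     utils::tail(assessed$timepoint, -1), sep = " -> "),
    overall = -diff(assessed$overall),
    control = -diff(assessed$control),
    intervention = -diff(assessed$intervention))
  cs <- lapply(seq_len(nrow(assessed)), function(i) {
    tp <- assessed$timepoint[i]
    tab <- table$items[[tp]]
    item_cols <- setdiff(names(tab), "child_id")
    ids <- tab$child_id[rowSums(!is.na(tab[, item_cols, drop = FALSE])) > 0]
    d <- m[match(ids, m$child_id), c("school_id", "arm")]
    out <- lapply(0:1, function(a) {
      sz <- table(d$school_id[d$arm == a & !is.na(d$arm)])
      data.frame(timepoint = tp, arm = a,
                 mean_cluster_size = if (length(sz)) mean(sz) else NA_real_,
                 sd_cluster_size = if (length(sz) > 1) stats::sd(sz) else
                   NA_real_)
    })
    do.call(rbind, out)
  })
  structure(list(funnel = funnel, assessed = assessed, lost_between = lost,
                 cluster_sizes = do.call(rbind, cs)),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat("Recruitment funnel:\n")
  print(x$funnel)
  cat("\nAssessed at each timepoint:\n")
  print(x$assessed)
  cat("\nCluster sizes by arm and timepoint:\n")
  print(x$cluster_sizes)
  invisible(x)
}

summarise_continuous <- function(x, skewed = FALSE) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  if (skewed) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
  } else {
    sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  }
}

#' Baseline characteristics by arm
#'
#' Continuous variables as mean (SD) — or median [IQR] for variables flagged
#' as skewed — and categorical variables as count (percent), by allocated
#' arm and overall, for enrolled children. Screening measures and scored
#' baseline instrument totals are included.
#'
#' @param table A `trial_table`.
#' @param skewed Character vector of variables to summarise as median [IQR].
#' @return Data frame with columns `variable`, `level`, `control`,
#'   `intervention`, `overall`.
#' @export
baseline_table <- function(table, skewed = character(0)) {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master[table$master$enrolled, , drop = FALSE]
  sc <- score_table(table)
  base <- sc[sc$timepoint == "t0", ]
  for (i in unique(base$instrument)) {
    v <- base[base$instrument == i, ]
    m[[paste0(i, "_t0")]] <- v$total[match(m$child_id, v$child_id)]
  }
  cont <- c("pas_screen", "stsc_screen", "gad7_screen", "imd_decile",
            "cluster_size", grep("_t0$", names(m), value = TRUE))
  cat_vars <- c("gender", "year_group", "fsm_stratum", "batch")
  rows <- list()
  groups <- list(control = m[m$arm == 0, ], intervention = m[m$arm == 1, ],
                 overall = m)
  for (v in cont) {
    if (!v %in% names(m)) next
    vals <- vapply(groups, function(g) {
      summarise_continuous(g[[v]], skewed = v %in% skewed)
    }, "")
    rows[[length(rows) + 1]] <- data.frame(variable = v, level = "",
                                           t(vals))
  }
  for (v in cat_vars) {
    lev <- sort(unique(m[[v]]))
    for (l in lev) {
      vals <- vapply(groups, function(g) {
        n <- sum(g[[v]] == l, na.rm = TRUE)
        sprintf("%d (%s%%)", n, fmt_pct(n / max(1, nrow(g))))
      }, "")
      rows[[length(rows) + 1]] <- data.frame(variable = v, level = as.character(l),
                                             t(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Missingness summary by outcome, timepoint and arm
#'
#' Percent of enrolled children with a missing (unscoreable) measure for
#' each instrument at each follow-up timepoint, by arm and overall, plus the
#' count of prorated (partially complete) totals reported separately.
#'
#' @param table A `trial_table`.
#' @return Data frame with columns `instrument`, `timepoint`, `arm`,
#'   `n`, `n_missing`, `pct_missing`, `n_prorated`.
#' @export
missingness_summary <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master[table$master$enrolled, , drop = FALSE]
  sc <- score_table(table)
  sc <- sc[sc$timepoint != "screening", ]
  sc$arm <- m$arm[match(sc$child_id, m$child_id)]
  rows <- list()
  for (tp in unique(sc$timepoint)) {
    for (inst in unique(sc$instrument[sc$timepoint == tp])) {
      v <- sc[sc$timepoint == tp & sc$instrument == inst, ]
      # children enrolled but absent from the timepoint table count missing
      for (a in list(0, 1, NA)) {
        ids <- if (is.na(a)) m$child_id else m$child_id[m$arm == a]
        present <- v[v$child_id %in% ids, ]
        n_tot <- length(ids)
        n_miss <- n_tot - sum(!is.na(present$total))
        rows[[length(rows) + 1]] <- data.frame(
          instrument = inst, timepoint = tp,
          arm = if (is.na(a)) "overall" else as.character(a),
          n = n_tot, n_missing = n_miss,
          pct_missing = as.numeric(fmt_pct(n_miss / max(1, n_tot))),
          n_prorated = sum(present$prorated & !is.na(present$total)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screening comparison of eligible participants and non-participants
#'
#' Among screen-positive (eligible) children, summarises the three screening
#' measures separately for those who enrolled and those who did not
#' (decliners, non-selected household siblings and non-responders), as a
#' descriptive assessment of noteworthy differences — no hypothesis tests.
#'
#' @param table A `trial_table`.
#' @return Data frame with one row per screening measure and group.
#' @export
nonparticipant_comparison <- function(table) {
  stopifnot(inherits(table, "trial_table"))
  m <- table$master
  elig <- m[m$screen_positive %in% TRUE, , drop = FALSE]
  if (nrow(elig) == 0) stop("no eligible children", call. = FALSE)
  groups <- list(participants = elig[elig$enrolled, ],
                 non_participants = elig[!elig$enrolled, ])
  measures <- c(pas = "pas_screen", stsc_a = "stsc_screen",
                gad7 = "gad7_screen")
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (nm in names(measures)) {
      x <- d[[measures[[nm]]]]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, measure = nm, n = nrow(d),
        mean = if (nrow(d)) mean(x, na.rm = TRUE) else NA_real_,
        sd = if (nrow(d) > 1) stats::sd(x, na.rm = TRUE) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (all(out$n[out$group == "non_participants"] == 0)) {
    attr(out, "note") <- "all eligible children participated"
  }
  rownames(out) <- NULL
  out
}
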