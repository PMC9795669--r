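# MAR missingness imposition and delimited-text serialisation of trial
# tables.

#' Impose missing-at-random missingness on a complete trial table
#'
#' Inserts measure-level missingness (a child's whole instrument at a
#' follow-up timepoint) and item-level missingness into the item tables.
#' Measure-level missingness probabilities depend only on *observed*
#' variables — allocated arm (centred) and the standardised baseline PAS
#' total — so the mechanism is missing-at-random by construction:
#' `logit(p) = logit(rate_t) + arm_coef * (arm - 0.5) + baseline_coef * z(PAS_t0)`.
#' Item-level missingness is independent Bernoulli per item. Latent
#' simulation-only fields are never blanked.
#'
#' @param table A complete `trial_table` from [generate_cohort()].
#' @param config The [sim_config()] whose `missingness` element holds
#'   `measure_rates` (named over `t1`, `t2`, `t3`), `item_rate`, `arm_coef`
#'   and `baseline_coef`. Rates of zero leave the table unchanged.
#' @return The trial table with `NA`s inserted into follow-up item tables.
#' @export
impose_missingness <- function(table, config) {
  stopifnot(inherits(table, "trial_table"), inherits(config, "sim_config"))
  ms <- config$missingness
  assert_prob(ms$measure_rates, "measure_rates")
  assert_prob(ms$item_rate, "item_rate")
  with_seed(derive_seed(config$seed, 3), {
    m <- table$master
    base_pas <- score_measure(
      as.matrix(table$items$t0[grep("^pas_i", names(table$items$t0))]),
      "pas")$total
    base_z <- as.numeric(scale(base_pas))
    base_z[is.na(base_z)] <- 0
    names(base_z) <- table$items$t0$child_id
    for (tp in intersect(names(ms$measure_rates), names(table$items))) {
      rate <- ms$measure_rates[[tp]]
      tab <- table$items[[tp]]
      if (is.null(tab) || nrow(tab) == 0) next
      arm <- m$arm[match(tab$child_id, m$child_id)]
      bz <- base_z[as.character(tab$child_id)]
      bz[is.na(bz)] <- 0
      lin <- stats::qlogis(pmin(pmax(rate, 1e-12), 1 - 1e-12)) +
        ms$arm_coef * (ifelse(is.na(arm), 0.5, arm) - 0.5) +
        ms$baseline_coef * bz
      p_measure <- if (rate <= 0) rep(0, nrow(tab)) else stats::plogis(lin)
      for (inst in .schedule[[tp]]) {
        cols <- grep(paste0("^", inst, "_i"), names(tab))
        if (!length(cols)) next
        drop_measure <- stats::runif(nrow(tab)) < p_measure
        if (any(drop_measure)) tab[drop_measure, cols] <- NA
        if (ms$item_rate > 0) {
          nm <- matrix(stats::runif(nrow(tab) * length(cols)),
                       nrow(tab)) < ms$item_rate
          block <- as.matrix(tab[, cols])
          block[nm] <- NA
          tab[, cols] <- block
        }
      }
      table$items[[tp]] <- tab
    }
    table
  })
}

#' Write a trial table as delimited text
#'
#' One comma-separated UTF-8 file per timepoint item table plus the
#' child-level master table and school roster; missing cells are written as
#' empty strings. The configuration (including the seed) is stored alongside
#' as JSON metadata.
#'
#' @param table A `trial_table`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_table <- function(table, dir) {
  stopifnot(inherits(table, "trial_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table$master, file.path(dir, "master.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(table$schools, file.path(dir, "schools.csv"),
                   row.names = FALSE, na = "")
  for (tp in names(table$items)) {
    utils::write.csv(table$items[[tp]], file.path(dir, paste0(tp, ".csv")),
                     row.names = FALSE, na = "")
  }
  cfg <- unclass(table$config)
  cfg$missingness$measure_rates <- as.list(cfg$missingness$measure_rates)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trial table written by [write_trial_table()]
#' @param dir Directory containing the delimited files.
#' @return A `trial_table`.
#' @export
read_trial_table <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), na.strings = "")
  files <- list.files(dir, pattern = "\\.csv$")
  tps <- setdiff(sub("\\.csv$", "", files), c("master", "schools"))
  items <- lapply(tps, function(tp) rd(paste0(tp, ".csv")))
  names(items) <- tps
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$missingness$measure_rates <- unlist(cfg$missingness$measure_rates)
  cfg$mediator_paths <- as.list(cfg$mediator_paths)
  class(cfg) <- "sim_config"
  ord <- c("screening", "t0", "t1", "t2", "t3")
  items <- items[intersect(ord, names(items))]
  structure(list(master = rd("master.csv"), items = items,
                 schools = rd("schools.csv"), config = cfg),
            class = "trial_table")
}
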