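#' Write an ASCN state frequency table as TSV
#'
#' @param freq Named numeric vector over state labels (e.g. from
#'   [control_state_frequencies()]).
#' @param path Output file.
#' @return Invisibly, the data frame written (columns `state`, `a_count`,
#'   `b_count`, `cn`, `freq`).
#' @export
write_state_table <- function(freq, path) {
  st <- parse_state(names(freq))
  st$freq <- as.numeric(freq)
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(st)
}

#' Read an ASCN state frequency table written by [write_state_table()]
#'
#' @param path Input TSV with columns `state`, `a_count`, `b_count`, `cn`,
#'   `freq`.
#' @return Named numeric vector of frequencies.
#' @export
read_state_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("state", "freq")
  if (!all(need %in% names(df))) {
    stop("state table must have columns: ", paste(need, collapse = ", "))
  }
  stats::setNames(df$freq, df$state)
}

#' Serialize scenario/risk grids to a YAML config
#'
#' Each entry carries the keys `f_norm`, `cnv_type`, `f_b`, `rr_cn`,
#' `rr_allele`, so one file can describe a full (frequency x risk) design.
#'
#' @param grid Data frame with any subset of those columns (e.g. the output
#'   of [frequency_scenario_grid()] merged with [risk_scenario_grid()]).
#' @param path Output YAML file.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(grid, path) {
  entries <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  entries <- lapply(entries, function(e) lapply(e, function(v) {
    if (is.factor(v)) as.character(v) else v
  }))
  yaml::write_yaml(list(scenarios = entries), path)
  invisible(path)
}

#' Read a scenario config written by [write_scenario_config()]
#'
#' @param path YAML file.
#' @return Data frame, one row per scenario entry.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios)) stop("config has no 'scenarios' key")
  do.call(rbind, lapply(cfg$scenarios, function(e) as.data.frame(e, stringsAsFactors = FALSE)))
}

#' Write a simulated cohort as TSV
#'
#' Columns: `individual_id`, `phenotype` (0 = control, 1 = case), `state`,
#' and `call` when bi-allelic genotype calls are present.
#'
#' @param cohort Cohort data frame (see [simulate_cohort()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c("individual_id", "phenotype", "state", "call"),
                    names(cohort))
  utils::write.table(cohort[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort TSV written by [write_cohort()]
#'
#' @param path Input file.
#' @return Cohort data frame with allele counts re-derived from the state
#'   labels.
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "phenotype", "state")
  if (!all(need %in% names(df))) {
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  }
  st <- parse_state(df$state)
  df$a_count <- st$a_count
  df$b_count <- st$b_count
  df$cn <- st$cn
  df
}

#' Write a bi-allelic call probability table as TSV
#'
#' @param table Call table matrix (15 states x 4 calls), see
#'   [default_call_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_call_table <- function(table, path) {
  df <- data.frame(state = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call probability table written by [write_call_table()]
#'
#' @param path Input TSV (columns `state`, `AA`, `AB`, `BB`, `missing`).
#' @return Call table matrix with state labels as row names.
#' @export
read_call_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, c("AA", "AB", "BB", "missing")])
  rownames(m) <- df$state
  validate_call_table(m)
  m
}
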