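#' Configuration for a power / type-I-error simulation study
#'
#' @param scenarios Data frame of frequency scenarios (columns `f_norm`,
#'   `cnv_type`, `f_b`), e.g. [frequency_scenario_grid()] or a subset.
#' @param risks Data frame of risk settings (columns `rr_cn`, `rr_allele`),
#'   e.g. [risk_scenario_grid()] or a subset.
#' @param n_cases,n_controls Per-replicate sample sizes.
#' @param n_reps Replicates per (scenario, risk) cell; the full design uses
#'   10,000, reduced presets (e.g. 1,000) give desk-scale reproductions.
#' @param strategies Strategies to fit each replicate.
#' @param alpha Significance level for the rejection count, default 0.05.
#' @param call_table Optional call probability table; required when
#'   `"allele_bi"` is among the strategies (states are degraded to bi-allelic
#'   calls each replicate).
#' @param error Optional [error_spec()]; when supplied, CNV calling errors
#'   are injected into the states before the state-based strategies run.
#' @param seed Master seed; per-replicate substream seeds are derived from it
#'   so results are independent of evaluation order.
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenarios, risks, n_cases = 1000L, n_controls = 1000L,
                         n_reps = 1000L,
                         strategies = c("cn", "allele_multi", "joint"),
                         alpha = 0.05, call_table = NULL, error = NULL,
                         seed = 1L) {
  strategies <- match.arg(strategies, several.ok = TRUE,
                          choices = c("cn", "allele_multi", "allele_bi",
                                      "joint", "codominant"))
  stopifnot(n_reps >= 1L, alpha > 0, alpha < 1,
            n_cases > 0L, n_controls > 0L)
  if ("allele_bi" %in% strategies && is.null(call_table)) {
    call_table <- default_call_table()
  }
  if (!is.null(call_table)) validate_call_table(call_table)
  if (!is.null(error)) stopifnot(inherits(error, "error_spec"))
  structure(list(scenarios = as.data.frame(scenarios),
                 risks = as.data.frame(risks),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_reps = as.integer(n_reps), strategies = strategies,
                 alpha = alpha, call_table = call_table, error = error,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run a power / type-I-error simulation study
#'
#' For every (frequency scenario, risk setting) cell, `n_reps` case-control
#' cohorts are simulated, optionally contaminated with CNV calling errors and
#' degraded to bi-allelic calls, and the requested strategies are fitted.
#' Power is the fraction of converged replicates with LRT p-value below
#' `alpha`. When the Joint strategy is run, the transformed odds ratios of
#' every converged replicate are summarized per cell.
#'
#' @param config A [study_config()].
#' @param progress Print a line per cell as the scan advances.
#' @return An object of class `ascn_power_table`: a list with `power` (one
#'   row per cell x strategy: rejection fraction, Monte-Carlo standard error,
#'   converged / failed replicate counts) and `estimates` (per cell medians,
#'   means and mean squared errors of the transformed Joint odds ratios), plus
#'   the `config`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  scen <- config$scenarios
  risks <- config$risks
  n_cells <- nrow(scen) * nrow(risks)
  cell_seeds <- matrix(derive_seeds(config$seed, n_cells * config$n_reps),
                       nrow = config$n_reps)
  strategies <- config$strategies
  power_rows <- vector("list", n_cells * length(strategies))
  est_rows <- vector("list", n_cells)
  cell <- 0L
  for (i in seq_len(nrow(scen))) {
    spec <- scenario_from_row(scen[i, ])
    for (j in seq_len(nrow(risks))) {
      risk <- risk_from_row(risks[j, ])
      cell <- cell + 1L
      res <- run_cell(spec, risk, config, cell_seeds[, cell])
      for (k in seq_along(strategies)) {
        s <- strategies[k]
        p <- res$p[, s]
        conv <- res$converged[, s]
        n_conv <- sum(conv)
        n_rej <- sum(p[conv] < config$alpha, na.rm = TRUE)
        pow <- if (n_conv > 0L) n_rej / n_conv else NA_real_
        power_rows[[(cell - 1L) * length(strategies) + k]] <- data.frame(
          f_norm = spec$f_norm, cnv_type = spec$cnv_type, f_b = spec$f_b,
          rr_cn = risk$rr_cn, rr_allele = risk$rr_allele, strategy = s,
          n_reps = config$n_reps, n_converged = n_conv,
          n_failed = config$n_reps - n_conv, n_rejected = n_rej,
          power = pow,
          mc_se = if (n_conv > 0L) sqrt(pow * (1 - pow) / n_conv) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
      if ("joint" %in% strategies) {
        conv <- res$converged[, "joint"]
        est <- estimate_summary(res$or_cn[conv], res$or_allele[conv],
                                rr_cn = risk$rr_cn, rr_allele = risk$rr_allele)
        est_rows[[cell]] <- cbind(
          data.frame(f_norm = spec$f_norm, cnv_type = spec$cnv_type,
                     f_b = spec$f_b, rr_cn = risk$rr_cn,
                     rr_allele = risk$rr_allele, stringsAsFactors = FALSE),
          est)
      }
      if (progress) {
        message(sprintf("cell %d/%d done (f_norm=%.3g %s f_b=%.2g rr_cn=%.2g rr_allele=%.2g)",
                        cell, n_cells, spec$f_norm, spec$cnv_type, spec$f_b,
                        risk$rr_cn, risk$rr_allele))
      }
    }
  }
  structure(list(power = do.call(rbind, power_rows),
                 estimates = if ("joint" %in% strategies)
                   do.call(rbind, est_rows) else NULL,
                 config = config),
            class = "ascn_power_table")
}

# One (scenario, risk) cell: n_reps replicates, light internal representation.
run_cell <- function(spec, risk, config, seeds) {
  ctrl <- control_state_frequencies(spec)
  case <- case_state_frequencies(ctrl, risk)
  st <- ascn_states()
  strategies <- config$strategies
  n_reps <- config$n_reps
  p <- matrix(NA_real_, n_reps, length(strategies),
              dimnames = list(NULL, strategies))
  converged <- matrix(FALSE, n_reps, length(strategies),
                      dimnames = list(NULL, strategies))
  or_cn <- rep(NA_real_, n_reps)
  or_allele <- rep(NA_real_, n_reps)
  needs_calls <- "allele_bi" %in% strategies
  # With neither genotype degradation nor error injection the per-individual
  # cohort is never inspected, so the replicate reduces to tabulated state
  # counts; the same fit kernels run either way.
  fast <- !needs_calls && is.null(config$error)
  for (r in seq_len(n_reps)) {
    rep_res <- run_with_seed(seeds[r], {
      idx_case <- sample.int(15L, config$n_cases, replace = TRUE, prob = case)
      idx_ctrl <- sample.int(15L, config$n_controls, replace = TRUE, prob = ctrl)
      if (fast) {
        y <- tabulate(idx_case, nbins = 15L)
        n <- y + tabulate(idx_ctrl, nbins = 15L)
        stats::setNames(lapply(strategies, fit_strategy_counts, y = y, n = n),
                        strategies)
      } else {
        cohort <- data.frame(
          individual_id = seq_len(config$n_cases + config$n_controls),
          phenotype = rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
          state = st$state[c(idx_case, idx_ctrl)],
          a_count = st$a_count[c(idx_case, idx_ctrl)],
          b_count = st$b_count[c(idx_case, idx_ctrl)],
          cn = st$cn[c(idx_case, idx_ctrl)],
          stringsAsFactors = FALSE
        )
        if (needs_calls) {
          cohort <- degrade_to_genotypes(cohort, config$call_table)
        }
        if (!is.null(config$error)) {
          cohort <- inject_errors(cohort, config$error)
        }
        fit_all_strategies(cohort, strategies)
      }
    })
    for (s in strategies) {
      f <- rep_res[[s]]
      converged[r, s] <- isTRUE(f$converged)
      p[r, s] <- f$p_value %||% NA_real_
    }
    if ("joint" %in% strategies) {
      or_cn[r] <- rep_res$joint$or_cn
      or_allele[r] <- rep_res$joint$or_allele
    }
  }
  list(p = p, converged = converged, or_cn = or_cn, or_allele = or_allele)
}

#' Summarize transformed Joint odds-ratio estimates over replicates
#'
#' @param or_cn,or_allele Numeric vectors of per-replicate transformed odds
#'   ratios from converged Joint fits.
#' @param rr_cn,rr_allele The simulated relative risks; the mean squared
#'   errors are computed against them.
#' @return One-row data frame with medians, means, MSEs and the number of
#'   converged replicates.
#' @export
estimate_summary <- function(or_cn, or_allele, rr_cn, rr_allele) {
  ok <- is.finite(or_cn) & is.finite(or_allele)
  or_cn <- or_cn[ok]; or_allele <- or_allele[ok]
  data.frame(
    n_converged = length(or_cn),
    median_or_cn = if (length(or_cn)) stats::median(or_cn) else NA_real_,
    median_or_allele = if (length(or_allele)) stats::median(or_allele) else NA_real_,
    mean_or_cn = if (length(or_cn)) mean(or_cn) else NA_real_,
    mean_or_allele = if (length(or_allele)) mean(or_allele) else NA_real_,
    mse_or_cn = if (length(or_cn)) mean((or_cn - rr_cn)^2) else NA_real_,
    mse_or_allele = if (length(or_allele)) mean((or_allele - rr_allele)^2) else NA_real_
  )
}

#' Relative power of one strategy against a reference strategy
#'
#' @param table An `ascn_power_table` from [run_study()], or its `power`
#'   data frame.
#' @param strategy,reference_strategy Strategy names present in the table.
#' @return Data frame with one row per (scenario, risk) cell: both powers,
#'   their ratio `relative_power` (NA with `reference_zero = TRUE` when the
#'   reference power is 0), and a delta-method standard error of the ratio.
#' @export
relative_power <- function(table, strategy, reference_strategy) {
  pw <- if (inherits(table, "ascn_power_table")) table$power else table
  if (!all(c(strategy, reference_strategy) %in% pw$strategy)) {
    stop("strategy not present in power table")
  }
  keys <- c("f_norm", "cnv_type", "f_b", "rr_cn", "rr_allele")
  a <- pw[pw$strategy == strategy, c(keys, "power", "mc_se", "n_converged")]
  b <- pw[pw$strategy == reference_strategy,
          c(keys, "power", "mc_se", "n_converged")]
  m <- merge(a, b, by = keys, suffixes = c("", "_ref"))
  m$relative_power <- ifelse(m$power_ref > 0, m$power / m$power_ref, NA_real_)
  m$reference_zero <- m$power_ref == 0
  # Delta method on the ratio of two independent binomial proportions.
  m$ratio_se <- ifelse(m$power_ref > 0 & m$power > 0,
    m$relative_power * sqrt(
      (1 - m$power) / (m$power * m$n_converged) +
      (1 - m$power_ref) / (m$power_ref * m$n_converged_ref)),
    NA_real_)
  m
}

#' @export
print.ascn_power_table <- function(x, ...) {
  cat(sprintf("ASCN power table: %d scenario(s) x %d risk setting(s), %d reps, strategies: %s\n",
              nrow(x$config$scenarios), nrow(x$config$risks),
              x$config$n_reps, paste(x$config$strategies, collapse = ", ")))
  print(utils::head(x$power, 10))
  if (nrow(x$power) > 10) cat("...", nrow(x$power), "rows total\n")
  invisible(x)
}

#' Write study outputs as TSV files
#'
#' @param table An `ascn_power_table`.
#' @param dir Output directory (created if needed); writes `power.tsv` and,
#'   when Joint estimates are present, `estimates.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(table, dir) {
  stopifnot(inherits(table, "ascn_power_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "power.tsv")
  utils::write.table(table$power, paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(table$estimates)) {
    ep <- file.path(dir, "estimates.tsv")
    utils::write.table(table$estimates, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, ep)
  }
  invisible(paths)
}
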