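#' Simulate a case-control ASCN cohort
#'
#' Controls are drawn i.i.d. from the control state distribution of the
#' scenario; cases from the case distribution implied by the risk model (see
#' [case_state_frequencies()]).
#'
#' @param spec A [scenario_spec()].
#' @param risk A [risk_model()].
#' @param n_cases,n_controls Positive sample sizes.
#' @param seed Optional integer seed; the draw is then reproducible and does
#'   not disturb the caller's RNG stream.
#' @return Cohort data frame with columns `individual_id`, `phenotype`
#'   (1 = case, 0 = control), `state`, `a_count`, `b_count`, `cn`. Cases come
#'   first.
#' @examples
#' co <- simulate_cohort(scenario_spec(0.5, "both", 0.35),
#'                       risk_model(1.5, 1), 100, 100, seed = 1)
#' table(co$phenotype)
#' @export
simulate_cohort <- function(spec, risk, n_cases, n_controls, seed = NULL) {
  stopifnot(n_cases > 0, n_controls > 0)
  ctrl <- control_state_frequencies(spec)
  case <- case_state_frequencies(ctrl, risk)
  st <- ascn_states()
  run_with_seed(seed, {
    idx <- c(sample.int(15L, n_cases, replace = TRUE, prob = case),
             sample.int(15L, n_controls, replace = TRUE, prob = ctrl))
    data.frame(
      individual_id = seq_len(n_cases + n_controls),
      phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
      state = st$state[idx],
      a_count = st$a_count[idx],
      b_count = st$b_count[idx],
      cn = st$cn[idx],
      stringsAsFactors = FALSE
    )
  })
}

#' Default bi-allelic calling probabilities per ASCN state
#'
#' A standard SNP-calling algorithm assumes every sample carries two copies,
#' so states with one or two copies are called essentially without error or
#' missingness, while zero-, three- and four-copy states produce noisy
#' intensity clusters and mostly missing calls. This default table encodes
#' that qualitative behaviour: one- and two-copy states map to their natural
#' call (`A -> AA`, `B -> BB`, `AA/AB/BB` unchanged) with a 0.5% missing
#' rate, and zero/three/four-copy states are missing at 60-85% with the
#' residual mass on compatible calls. The heterozygous three- and four-copy
#' states are given deliberately asymmetric missing rates (`AAB` vs `ABB`,
#' `AAAB` vs `ABBB`), reflecting the dye/intensity bias seen on real arrays.
#'
#' The table is a synthetic default, not an estimate from any particular
#' array: calibrate it on your own platform (observed ASCN state vs Beadstudio
#' or Birdseed call) and pass the result to [degrade_to_genotypes()], or edit
#' a copy written by [write_call_table()].
#'
#' @return A 15 x 4 matrix of probabilities, rows the canonical state labels,
#'   columns `AA`, `AB`, `BB`, `missing`; each row sums to 1.
#' @examples
#' default_call_table()["AB", ]
#' @export
default_call_table <- function() {
  st <- ascn_states()$state
  m <- matrix(0, nrow = 15, ncol = 4,
              dimnames = list(st, c("AA", "AB", "BB", "missing")))
  m["NULL", ] <- c(0.05, 0.05, 0.05, 0.85)
  m["A", ] <- c(0.995, 0, 0, 0.005)
  m["B", ] <- c(0, 0, 0.995, 0.005)
  m["AA", ] <- c(0.995, 0, 0, 0.005)
  m["AB", ] <- c(0, 0.995, 0, 0.005)
  m["BB", ] <- c(0, 0, 0.995, 0.005)
  m["AAA", ] <- c(0.35, 0, 0, 0.65)
  m["AAB", ] <- c(0.15, 0.25, 0, 0.60)
  m["ABB", ] <- c(0, 0.20, 0.10, 0.70)
  m["BBB", ] <- c(0, 0, 0.35, 0.65)
  m["AAAA", ] <- c(0.30, 0, 0, 0.70)
  m["AAAB", ] <- c(0.10, 0.20, 0, 0.70)
  m["AABB", ] <- c(0, 0.30, 0, 0.70)
  m["ABBB", ] <- c(0, 0.12, 0.08, 0.80)
  m["BBBB", ] <- c(0, 0, 0.30, 0.70)
  validate_call_table(m)
  m
}

validate_call_table <- function(table) {
  if (!is.matrix(table) || ncol(table) != 4L ||
      !identical(colnames(table), c("AA", "AB", "BB", "missing"))) {
    stop("call table must be a matrix with columns AA, AB, BB, missing")
  }
  if (any(table < 0) || any(table > 1)) {
    stop("call table entries must be probabilities in [0, 1]")
  }
  if (any(abs(rowSums(table) - 1) > 1e-9)) {
    stop("call table rows must sum to 1")
  }
  invisible(table)
}

#' Degrade ASCN states to bi-allelic genotype calls
#'
#' For each individual, draws a call (`AA`, `AB`, `BB` or `missing`) from the
#' call-table row of its ASCN state, emulating what a standard two-copy SNP
#' caller would report.
#'
#' @param cohort Cohort data frame from [simulate_cohort()].
#' @param table Call probability table, default [default_call_table()].
#' @param seed Optional integer seed.
#' @return The cohort with an added `call` column.
#' @export
degrade_to_genotypes <- function(cohort, table = default_call_table(),
                                 seed = NULL) {
  validate_call_table(table)
  if (!all(cohort$state %in% rownames(table))) {
    stop("call table lacks rows for states: ",
         paste(setdiff(unique(cohort$state), rownames(table)), collapse = ", "))
  }
  calls <- colnames(table)
  run_with_seed(seed, {
    out <- character(nrow(cohort))
    for (s in unique(cohort$state)) {
      i <- which(cohort$state == s)
      out[i] <- calls[sample.int(4L, length(i), replace = TRUE,
                                 prob = table[s, ])]
    }
    cohort$call <- out
    cohort
  })
}

#' CNV detection error specification
#'
#' @param sensitivity Probability that a true CNV carrier (total copies not
#'   equal to 2) is detected as such; SNP-array CNV calling is insensitive,
#'   with typical values around 0.2-0.5.
#' @param specificity Probability that a true two-copy individual is *not*
#'   falsely called a CNV carrier; default 0.99.
#' @return An object of class `error_spec`.
#' @examples
#' error_spec(0.5)
#' @export
error_spec <- function(sensitivity, specificity = 0.99) {
  stopifnot(is.numeric(sensitivity), length(sensitivity) == 1L,
            sensitivity >= 0, sensitivity <= 1,
            is.numeric(specificity), length(specificity) == 1L,
            specificity >= 0, specificity <= 1)
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "error_spec")
}

#' Inject CNV calling errors into an ASCN cohort
#'
#' Applies the two-sided error model of imperfect CNV detection to the
#' recorded ASCN states:
#'
#' * A true CNV carrier (total copies different from 2) is *missed* with
#'   probability `1 - sensitivity`; its recorded state collapses to a
#'   two-copy genotype: `AA` or `BB` if the state is homozygous, `AB` if
#'   heterozygous, and uniformly one of `AA`/`AB`/`BB` for the zero-copy
#'   `NULL` state.
#' * A true two-copy individual is *falsely flagged* with probability
#'   `1 - specificity`; a wrong copy number is drawn uniformly from
#'   {0, 1, 3, 4} and the recorded state is remapped preserving the original
#'   allele content: `AA -> A / AAA / AAAA`, `BB -> B / BBB / BBBB`,
#'   `AB -> {A, B} / {AAB, ABB} / {AAAB, AABB, ABBB}` (uniform within each
#'   set), and any state becomes `NULL` for a wrong copy number of 0.
#'
#' @param cohort Cohort data frame from [simulate_cohort()].
#' @param err An [error_spec()].
#' @param seed Optional integer seed.
#' @return The cohort with `state`, `a_count`, `b_count`, `cn` replaced by the
#'   error-contaminated values.
#' @export
inject_errors <- function(cohort, err, seed = NULL) {
  stopifnot(inherits(err, "error_spec"))
  run_with_seed(seed, {
    state <- cohort$state
    a <- cohort$a_count
    b <- cohort$b_count
    cn <- cohort$cn

    # Missed true CNVs.
    is_cnv <- which(cn != 2L)
    if (length(is_cnv)) {
      missed <- is_cnv[stats::runif(length(is_cnv)) >= err$sensitivity]
      if (length(missed)) {
        het <- a[missed] > 0L & b[missed] > 0L
        all_a <- b[missed] == 0L & a[missed] > 0L
        all_b <- a[missed] == 0L & b[missed] > 0L
        nullst <- a[missed] == 0L & b[missed] == 0L
        state[missed[het]] <- "AB"
        state[missed[all_a]] <- "AA"
        state[missed[all_b]] <- "BB"
        if (any(nullst)) {
          state[missed[nullst]] <- sample(c("AA", "AB", "BB"),
                                          sum(nullst), replace = TRUE)
        }
      }
    }

    # Falsely flagged two-copy individuals.
    is_two <- which(cn == 2L)
    if (length(is_two)) {
      fp <- is_two[stats::runif(length(is_two)) >= err$specificity]
      if (length(fp)) {
        wrong_cn <- sample(c(0L, 1L, 3L, 4L), length(fp), replace = TRUE)
        state[fp] <- mapply(remap_false_positive, state[fp], wrong_cn,
                            USE.NAMES = FALSE)
      }
    }

    st <- parse_state(state)
    cohort$state <- st$state
    cohort$a_count <- st$a_count
    cohort$b_count <- st$b_count
    cohort$cn <- st$cn
    cohort
  })
}

# Remap a two-copy state to a falsely detected wrong copy number; one random
# draw may be consumed for heterozygous AB.
remap_false_positive <- function(state, wrong_cn) {
  if (wrong_cn == 0L) return("NULL")
  switch(state,
    AA = c(`1` = "A", `3` = "AAA", `4` = "AAAA")[[as.character(wrong_cn)]],
    BB = c(`1` = "B", `3` = "BBB", `4` = "BBBB")[[as.character(wrong_cn)]],
    AB = sample(switch(as.character(wrong_cn),
                       `1` = c("A", "B"),
                       `3` = c("AAB", "ABB"),
                       `4` = c("AAAB", "AABB", "ABBB")), 1L),
    stop("false-positive remap applies only to two-copy states, got ", state)
  )
}
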