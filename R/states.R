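#' The allele-specific copy number state space
#'
#' An allele-specific copy number (ASCN) state is the unordered multiset of
#' SNP alleles an individual carries at a locus inside a CNV region: with two
#' alleles A and B and total copy numbers 0 to 4 there are exactly 15 states
#' (`NULL`, `A`, `B`, `AA`, `AB`, `BB`, ..., `BBBB`). States carry no phase
#' information: `ABB` covers both the (AB, B) and (A, BB) chromosome
#' configurations.
#'
#' @return A data frame with one row per state, in canonical order (by total
#'   copy number `cn`, then by `b_count`), with columns `state` (label such as
#'   `"ABB"`, `"NULL"` for the zero-copy state), `a_count`, `b_count` and
#'   `cn = a_count + b_count`.
#' @examples
#' ascn_states()
#' @export
ascn_states <- function() {
  if (is.null(.ascn_cache$states)) {
    cn <- rep.int(0:4, 1:5)
    b <- unlist(lapply(0:4, function(k) 0:k), use.names = FALSE)
    a <- cn - b
    .ascn_cache$states <- data.frame(
      state = state_label(a, b),
      a_count = a,
      b_count = b,
      cn = cn,
      stringsAsFactors = FALSE
    )
  }
  .ascn_cache$states
}

.ascn_cache <- new.env(parent = emptyenv())

#' Build ASCN state labels from allele counts
#'
#' @param a_count,b_count Non-negative integer vectors of copies of allele A
#'   and allele B; `a_count + b_count` must not exceed 4.
#' @return Character labels, `"NULL"` for the zero-copy state.
#' @examples
#' state_label(1, 2) # "ABB"
#' @export
state_label <- function(a_count, b_count) {
  stopifnot(all(a_count >= 0), all(b_count >= 0), all(a_count + b_count <= 4))
  out <- mapply(function(a, b) {
    if (a + b == 0L) "NULL" else paste0(strrep("A", a), strrep("B", b))
  }, a_count, b_count, USE.NAMES = FALSE)
  as.character(out)
}

#' Parse ASCN state labels into allele counts
#'
#' @param state Character vector of labels such as `"AAB"` or `"NULL"`.
#' @return Data frame with columns `state`, `a_count`, `b_count`, `cn`.
#' @examples
#' parse_state(c("NULL", "ABB"))
#' @export
parse_state <- function(state) {
  ok <- state == "NULL" | grepl("^A{0,4}B{0,4}$", state)
  if (any(!ok)) {
    stop("invalid ASCN state label(s): ", paste(unique(state[!ok]), collapse = ", "))
  }
  a <- ifelse(state == "NULL", 0L, nchar(gsub("B", "", state)))
  b <- ifelse(state == "NULL", 0L, nchar(gsub("A", "", state)))
  if (any(a + b > 4L) || any(a + b == 0L & state != "NULL")) {
    stop("ASCN states must have total copy number between 0 and 4")
  }
  data.frame(state = state, a_count = a, b_count = b, cn = a + b,
             stringsAsFactors = FALSE)
}

#' Frequency scenario for a SNP inside a common CNV
#'
#' A scenario fixes the population frequency structure at one locus: the
#' frequency `f_norm` of chromosomes carrying the normal single copy of the
#' region, which type(s) of CNV segregate (deletions removing the copy,
#' duplications doubling it, or both), and the B allele frequency `f_b`.
#' Deletion and duplication chromosome frequencies are derived: with a single
#' CNV type the variant chromosome has frequency `1 - f_norm`; with both
#' types present, deletions and duplications are equally frequent,
#' `f_del = f_dup = (1 - f_norm) / 2`.
#'
#' @param f_norm Frequency of normal one-copy chromosomes, in (0, 1].
#' @param cnv_type One of `"del"` (deletions only), `"dup"` (duplications
#'   only) or `"both"`.
#' @param f_b B allele frequency, in (0, 1).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec(0.5, "both", 0.35)
#' @export
scenario_spec <- function(f_norm, cnv_type = c("both", "del", "dup"), f_b) {
  cnv_type <- match.arg(cnv_type)
  if (!is.numeric(f_norm) || length(f_norm) != 1L || f_norm <= 0 || f_norm > 1) {
    stop("invalid scenario: f_norm must lie in (0, 1]")
  }
  if (!is.numeric(f_b) || length(f_b) != 1L || f_b <= 0 || f_b >= 1) {
    stop("invalid scenario: f_b must lie in (0, 1)")
  }
  structure(list(f_norm = f_norm, cnv_type = cnv_type, f_b = f_b),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  fr <- chromosome_frequencies(x)
  cat(sprintf(
    "ASCN frequency scenario: f(norm) = %.4g, CNV type = %s, f(B) = %.4g\n",
    x$f_norm, x$cnv_type, x$f_b))
  cat(sprintf("  chromosome frequencies: f(del) = %.4g, f(norm) = %.4g, f(dup) = %.4g\n",
              fr[["del"]], fr[["norm"]], fr[["dup"]]))
  invisible(x)
}

#' Multiplicative relative-risk model on ASCN states
#'
#' Disease risk is modelled multiplicatively in the total copy number and the
#' number of B alleles, with the two-copy `AA` state as reference:
#' `RR(state) = rr_cn^(cn - 2) * rr_allele^(b_count)`. `rr_cn` is the relative
#' risk per extra copy of the region (reference two copies); `rr_allele` the
#' relative risk per extra B allele (reference zero). `(1, 1)` is the global
#' null of no association.
#'
#' The zero-copy `NULL` state has no alleles at all; by default the
#' multiplicative formula is applied to it as well, giving `rr_cn^(-2)`.
#' Supply `null_state_rr` to override that choice.
#'
#' @param rr_cn Relative risk per extra copy, positive.
#' @param rr_allele Relative risk per extra B allele, positive.
#' @param null_state_rr Optional positive relative risk for the `NULL` state;
#'   default `NULL` applies the multiplicative formula (`rr_cn^(-2)`).
#' @return An object of class `risk_model`.
#' @examples
#' risk_model(1.5, 1.2)
#' @export
risk_model <- function(rr_cn = 1, rr_allele = 1, null_state_rr = NULL) {
  stopifnot(is.numeric(rr_cn), length(rr_cn) == 1L, rr_cn > 0,
            is.numeric(rr_allele), length(rr_allele) == 1L, rr_allele > 0)
  if (!is.null(null_state_rr)) {
    stopifnot(is.numeric(null_state_rr), length(null_state_rr) == 1L,
              null_state_rr > 0)
  }
  structure(list(rr_cn = rr_cn, rr_allele = rr_allele,
                 null_state_rr = null_state_rr),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("ASCN risk model: RR_CN = %.4g, RR_allele = %.4g%s\n",
              x$rr_cn, x$rr_allele,
              if (is.null(x$null_state_rr)) ""
              else sprintf(", RR(NULL) = %.4g", x$null_state_rr)))
  invisible(x)
}

#' Chromosome-level frequencies implied by a scenario
#'
#' @param spec A [scenario_spec()].
#' @return Named numeric vector `c(del=, norm=, dup=)`, summing to 1.
#' @examples
#' chromosome_frequencies(scenario_spec(0.5, "both", 0.2))
#' @export
chromosome_frequencies <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  rest <- 1 - spec$f_norm
  fr <- switch(spec$cnv_type,
    del  = c(del = rest, norm = spec$f_norm, dup = 0),
    dup  = c(del = 0, norm = spec$f_norm, dup = rest),
    both = c(del = rest / 2, norm = spec$f_norm, dup = rest / 2)
  )
  fr
}

#' Population distribution of the total copy number
#'
#' Each individual carries two chromosomes, each bearing 0 (deleted), 1
#' (normal) or 2 (duplicated) copies of the region; the total copy number is
#' the sum over the pair, so e.g. `P(CN = 0) = f_del^2` and
#' `P(CN = 2) = f_norm^2 + 2 f_del f_dup`.
#'
#' @param spec A [scenario_spec()].
#' @return Named numeric vector of length 5 (`"0"` to `"4"`), summing to 1.
#' @examples
#' copy_number_distribution(scenario_spec(0.5, "both", 0.2))
#' @export
copy_number_distribution <- function(spec) {
  q <- chromosome_frequencies(spec) # copies 0, 1, 2 per chromosome
  p <- numeric(5)
  for (i in 0:2) for (j in 0:2) {
    p[i + j + 1L] <- p[i + j + 1L] + q[[i + 1L]] * q[[j + 1L]]
  }
  names(p) <- as.character(0:4)
  p
}

#' ASCN state frequencies in the control population
#'
#' Combines the copy-number distribution with independent allele draws: given
#' `c` total copies, the number of B alleles is binomial `(c, f_b)`, so the
#' state with `c` copies and `b` B alleles has probability
#' `P(CN = c) * choose(c, b) * f_b^b * (1 - f_b)^(c - b)`; the `NULL` state
#' gets `P(CN = 0)`.
#'
#' @param spec A [scenario_spec()].
#' @return Named numeric vector over the 15 canonical state labels, summing
#'   to 1.
#' @examples
#' control_state_frequencies(scenario_spec(0.8, "del", 0.5))
#' @export
control_state_frequencies <- function(spec) {
  st <- ascn_states()
  pcn <- copy_number_distribution(spec)
  p <- pcn[st$cn + 1L] * stats::dbinom(st$b_count, st$cn, spec$f_b)
  names(p) <- st$state
  p
}

#' Relative risk of each ASCN state under the multiplicative model
#'
#' @param state Character vector of state labels, or a data frame with
#'   `a_count` and `b_count` columns (e.g. from [ascn_states()]).
#' @param risk A [risk_model()].
#' @return Numeric vector of relative risks versus the `AA` reference state.
#' @examples
#' state_relative_risk("ABB", risk_model(1.2, 1.5)) # 1.2 * 1.5^2 = 2.7
#' @export
state_relative_risk <- function(state, risk) {
  stopifnot(inherits(risk, "risk_model"))
  st <- if (is.data.frame(state)) state else parse_state(state)
  rr <- risk$rr_cn^(st$a_count + st$b_count - 2) * risk$rr_allele^st$b_count
  if (!is.null(risk$null_state_rr)) {
    rr[st$a_count + st$b_count == 0L] <- risk$null_state_rr
  }
  stats::setNames(rr, if (is.data.frame(state)) state$state else state)
}

#' ASCN state frequencies in the case population
#'
#' Case frequencies follow from the control frequencies and the per-state
#' relative risks by reweighting:
#' `P_case(g) = P_ctrl(g) RR(g) / sum_g' P_ctrl(g') RR(g')`.
#'
#' @param ctrl Named numeric vector of control state frequencies over the 15
#'   canonical labels (see [control_state_frequencies()]); must sum to 1.
#' @param risk A [risk_model()].
#' @return Named numeric vector of case state frequencies, summing to 1.
#' @examples
#' ctrl <- control_state_frequencies(scenario_spec(0.5, "both", 0.2))
#' case_state_frequencies(ctrl, risk_model(1.5, 1.2))
#' @export
case_state_frequencies <- function(ctrl, risk) {
  if (is.null(names(ctrl))) stop("ctrl must be a named state distribution")
  if (abs(sum(ctrl) - 1) > 1e-8 || any(ctrl < 0)) {
    stop("ctrl must be a probability distribution over ASCN states")
  }
  rr <- state_relative_risk(names(ctrl), risk)
  w <- ctrl * rr
  w / sum(w)
}

#' The 36-point grid of frequency scenarios
#'
#' Cartesian product of `f_norm` in {0.8, 0.5, 1/3}, the three CNV types
#' (deletions only, duplications only, both) and `f_b` in
#' {0.05, 0.20, 0.35, 0.50}.
#'
#' @return Data frame with 36 rows and columns `f_norm`, `cnv_type`, `f_b`.
#' @examples
#' nrow(frequency_scenario_grid()) # 36
#' @export
frequency_scenario_grid <- function() {
  g <- expand.grid(
    f_b = c(0.05, 0.20, 0.35, 0.50),
    cnv_type = c("del", "dup", "both"),
    f_norm = c(0.8, 0.5, 1 / 3),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g[, c("f_norm", "cnv_type", "f_b")]
}

#' The 16-point grid of risk scenarios
#'
#' Cartesian product of `RR_CN` and `RR_allele` over {1, 1.2, 1.5, 2},
#' including the global null (1, 1).
#'
#' @return Data frame with 16 rows and columns `rr_cn`, `rr_allele`.
#' @examples
#' nrow(risk_scenario_grid()) # 16
#' @export
risk_scenario_grid <- function() {
  g <- expand.grid(rr_allele = c(1, 1.2, 1.5, 2), rr_cn = c(1, 1.2, 1.5, 2),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("rr_cn", "rr_allele")]
}

# Row of a scenario/risk grid -> typed object
scenario_from_row <- function(row) {
  scenario_spec(row$f_norm, row$cnv_type, row$f_b)
}

risk_from_row <- function(row) {
  risk_model(row$rr_cn, row$rr_allele)
}
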