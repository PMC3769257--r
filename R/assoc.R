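# The five association strategies, all logistic-regression likelihood-ratio
# tests of phenotype (1 = case, 0 = control) on covariates built from the
# ASCN state or from the bi-allelic genotype call:
#
#   CN            logit(p) ~ a + b (A + B)        1 df   H0: OR_CN = 1
#   Allele (bi)   logit(p) ~ a + b (B in call)    1 df   H0: OR_allele = 1
#   Allele (multi)logit(p) ~ a + b (B in state)   1 df   H0: OR_allele = 1
#   Joint         logit(p) ~ a + b1 (A+B) + b2 (A-B)  2 df
#   Codominant    logit(p) ~ a + sum_i b_i 1{state_i}, reference AA
#
# Individuals sharing a covariate pattern are pooled, so the fits run on a
# handful of binomial rows; the reported log-likelihoods are nevertheless the
# per-individual Bernoulli log-likelihoods, and LRT statistics are identical
# to the ungrouped fit.

# Grouped logistic fit. X: groups x k covariate matrix (no intercept);
# y = cases per group, n = individuals per group.
fit_grouped_logistic <- function(X, y, n) {
  keep <- n > 0
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- n[keep]
  Xd <- cbind(`(Intercept)` = 1, X)
  rank_needed <- ncol(Xd)
  if (qr(Xd)$rank < rank_needed) {
    return(list(coef = stats::setNames(rep(NA_real_, rank_needed), colnames(Xd)),
                se = rep(NA_real_, rank_needed), loglik = NA_real_,
                converged = FALSE, separated = FALSE,
                note = "degenerate or collinear covariates"))
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y / n, weights = n, family = stats::binomial())
  )
  p <- fit$fitted.values
  ll <- bernoulli_loglik(y, n, p)
  separated <- all(pmin(p, 1 - p) < 1e-6)
  vc <- tryCatch({
    w <- n * p * (1 - p)
    solve(crossprod(Xd, w * Xd))
  }, error = function(e) matrix(NA_real_, rank_needed, rank_needed))
  list(coef = stats::setNames(fit$coefficients, colnames(Xd)),
       se = sqrt(pmax(diag(vc), 0)), loglik = ll,
       converged = isTRUE(fit$converged) && !separated,
       separated = separated, note = NULL)
}

bernoulli_loglik <- function(y, n, p) {
  t1 <- ifelse(y > 0, y * log(p), 0)
  t2 <- ifelse(n - y > 0, (n - y) * log1p(-p), 0)
  sum(t1 + t2)
}

# Intercept-only log-likelihood (closed form).
null_loglik <- function(y, n) {
  ycase <- sum(y); ntot <- sum(n)
  p0 <- ycase / ntot
  bernoulli_loglik(ycase, ntot, p0)
}

new_ascn_fit <- function(strategy, n_used, grouped, ll0, df, extra = list()) {
  llf <- grouped$loglik
  lrt <- if (is.na(llf)) NA_real_ else max(0, 2 * (llf - ll0))
  p <- if (grouped$converged && !is.na(lrt)) {
    stats::pchisq(lrt, df = df, lower.tail = FALSE)
  } else NA_real_
  structure(c(list(
    strategy = strategy,
    n_used = n_used,
    coefficients = grouped$coef,
    se = grouped$se,
    loglik_null = ll0,
    loglik_full = llf,
    lrt = lrt,
    df = df,
    p_value = p,
    converged = grouped$converged,
    separated = grouped$separated,
    note = grouped$note
  ), extra), class = "ascn_fit")
}

#' @export
print.ascn_fit <- function(x, ...) {
  cat(sprintf("ASCN association fit: %s strategy (n = %d)\n",
              x$strategy, x$n_used))
  if (!x$converged) {
    cat("  fit did not converge",
        if (!is.null(x$note)) paste0(" (", x$note, ")"), "\n", sep = "")
  }
  if (!is.na(x$lrt)) {
    cat(sprintf("  LRT = %.4g on %d df, p = %.4g\n", x$lrt, x$df,
                x$p_value %||% NA_real_))
  }
  co <- x$coefficients
  cat("  coefficients:", paste(sprintf("%s = %.4g", names(co), co),
                               collapse = ", "), "\n")
  if (!is.null(x$or_cn)) {
    cat(sprintf("  transformed odds ratios: OR_CN = %.4g, OR_allele = %.4g\n",
                x$or_cn, x$or_allele))
  }
  invisible(x)
}

check_cohort <- function(cohort) {
  need <- c("phenotype", "state", "a_count", "b_count", "cn")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(cohort$phenotype)) < 2L) {
    stop("cohort must contain both cases and controls")
  }
  invisible(cohort)
}

# Aggregate a cohort by ASCN state -> per-state case/total counts aligned to
# the canonical 15-state table (states absent from the cohort get n = 0).
state_counts <- function(cohort) {
  st <- ascn_states()
  idx <- match(cohort$state, st$state)
  y <- tabulate(idx[cohort$phenotype == 1L], nbins = 15L)
  n <- tabulate(idx, nbins = 15L)
  list(states = st, y = y, n = n)
}

# State-based strategies expressed on per-state case/total counts (y, n over
# the 15 canonical states). The public fit_* functions aggregate a cohort and
# dispatch here; the study engine calls this directly from tabulated draws.
fit_strategy_counts <- function(strategy, y, n, n_used = sum(n)) {
  st <- ascn_states()
  ll0 <- null_loglik(y, n)
  if (strategy == "cn" || strategy == "allele_multi") {
    cov <- if (strategy == "cn") st$cn else st$b_count
    nm <- if (strategy == "cn") "cn" else "b_count"
    X <- matrix(cov, ncol = 1, dimnames = list(NULL, nm))
    g <- fit_grouped_logistic(X, y, n)
    return(new_ascn_fit(strategy, n_used, g, ll0, df = 1L))
  }
  if (strategy == "joint") {
    X <- cbind(sum = st$cn, diff = st$a_count - st$b_count)
    g <- fit_grouped_logistic(X, y, n)
    ors <- if (g$converged) transform_joint(g$coef[["sum"]], g$coef[["diff"]])
           else c(or_cn = NA_real_, or_allele = NA_real_)
    return(new_ascn_fit("joint", n_used, g, ll0, df = 2L,
                        extra = list(or_cn = ors[["or_cn"]],
                                     or_allele = ors[["or_allele"]])))
  }
  if (strategy == "codominant") {
    obs <- which(n > 0L)
    if (length(obs) < 2L) stop("codominant model needs at least 2 observed states")
    labels <- st$state[obs]
    note <- NULL
    if ("AA" %in% labels) {
      ref <- "AA"
    } else {
      ref <- labels[which.max(n[obs])]
      note <- sprintf("reference AA unobserved; using %s", ref)
    }
    others <- setdiff(labels, ref)
    X <- matrix(0, nrow = length(obs), ncol = length(others),
                dimnames = list(NULL, others))
    for (k in seq_along(others)) X[labels == others[k], k] <- 1
    g <- fit_grouped_logistic(X, y[obs], n[obs])
    if (!is.null(note)) g$note <- paste(c(g$note, note), collapse = "; ")
    return(new_ascn_fit("codominant", n_used, g, ll0, df = length(obs) - 1L))
  }
  stop("unknown strategy: ", strategy)
}

# Shared driver for the state-based trend strategies.
fit_state_trend <- function(cohort, strategy) {
  check_cohort(cohort)
  sc <- state_counts(cohort)
  fit_strategy_counts(strategy, sc$y, sc$n, n_used = nrow(cohort))
}

#' CN strategy: trend test on the total copy number
#'
#' Logistic regression of case status on the total copy number (0-4) carried
#' at the locus, a 1-df likelihood-ratio test of `OR_CN = 1`.
#'
#' @param cohort Cohort data frame (see [simulate_cohort()]).
#' @return An `ascn_fit` object.
#' @export
fit_cn <- function(cohort) {
  fit_state_trend(cohort, "cn")
}

#' Allele (multi) strategy: trend test on the B allele count in the ASCN state
#'
#' Logistic regression of case status on the number of B alleles (0-4) in the
#' allele-specific copy number state, a 1-df likelihood-ratio test of
#' `OR_allele = 1`.
#'
#' @inheritParams fit_cn
#' @return An `ascn_fit` object.
#' @export
fit_allele_multi <- function(cohort) {
  fit_state_trend(cohort, "allele_multi")
}

#' Allele (bi) strategy: trend test on the bi-allelic genotype call
#'
#' The classical SNP analysis: logistic regression of case status on the
#' number of B alleles in the bi-allelic call (`AA` = 0, `AB` = 1, `BB` = 2),
#' individuals with missing calls excluded; a 1-df likelihood-ratio test.
#'
#' @param cohort Cohort data frame with a `call` column (see
#'   [degrade_to_genotypes()]).
#' @return An `ascn_fit` object; `n_used` counts the non-missing individuals.
#' @export
fit_allele_bi <- function(cohort) {
  check_cohort(cohort)
  if (is.null(cohort$call)) stop("cohort has no bi-allelic 'call' column")
  keep <- !is.na(cohort$call) & cohort$call != "missing"
  if (!any(keep)) stop("all bi-allelic calls are missing")
  calls <- cohort$call[keep]
  pheno <- cohort$phenotype[keep]
  bad <- setdiff(unique(calls), c("AA", "AB", "BB"))
  if (length(bad)) stop("invalid bi-allelic calls: ", paste(bad, collapse = ", "))
  idx <- match(calls, c("AA", "AB", "BB"))
  y <- tabulate(idx[pheno == 1L], nbins = 3L)
  n <- tabulate(idx, nbins = 3L)
  if (sum(y) == 0L || sum(y) == sum(n)) {
    g <- list(coef = c(`(Intercept)` = NA_real_, b = NA_real_),
              se = c(NA_real_, NA_real_), loglik = NA_real_,
              converged = FALSE, separated = FALSE,
              note = "single phenotype after excluding missing calls")
    return(new_ascn_fit("allele_bi", sum(n), g, NA_real_, df = 1L))
  }
  X <- matrix(0:2, ncol = 1, dimnames = list(NULL, "b_count"))
  g <- fit_grouped_logistic(X, y, n)
  new_ascn_fit("allele_bi", sum(n), g, null_loglik(y, n), df = 1L)
}

#' Joint strategy: 2-df sum/difference test of allele and copy-number effects
#'
#' Logistic regression of case status on the sum `S = A + B` (total copies)
#' and the difference `D = A - B` of the two allele counts, compared to the
#' intercept-only model by a 2-df likelihood-ratio test. The raw coefficients
#' mix the two effects; [transform_joint()] recovers the odds ratios
#' `OR_CN` and `OR_allele` and the returned fit already carries them as
#' `or_cn` / `or_allele`.
#'
#' @inheritParams fit_cn
#' @return An `ascn_fit` object with elements `or_cn` and `or_allele`.
#' @export
fit_joint <- function(cohort) {
  fit_state_trend(cohort, "joint")
}

#' Codominant strategy: one indicator per observed ASCN state
#'
#' Logistic regression with a separate effect for every allele-specific copy
#' number state observed in the cohort, `AA` as reference; the
#' likelihood-ratio test has (number of observed states - 1) degrees of
#' freedom. When `AA` itself is unobserved the most frequent observed state
#' serves as reference and the fit is annotated.
#'
#' @inheritParams fit_cn
#' @return An `ascn_fit` object.
#' @export
fit_codominant <- function(cohort) {
  fit_state_trend(cohort, "codominant")
}

#' Recover OR_CN and OR_allele from the Joint model coefficients
#'
#' With covariates `S = A + B` and `D = A - B`, the log-odds of a state with
#' `c` copies and `b` B alleles under the multiplicative risk model is
#' `const + (c - 2) log OR_CN + b log OR_allele`; substituting `c = S` and
#' `b = (S - D) / 2` shows the sum coefficient estimates
#' `log OR_CN + log(OR_allele)/2` (the copy-number effect plus half of the B
#' allele effect) and the difference coefficient estimates
#' `-log(OR_allele)/2`. Inverting:
#' `OR_allele = exp(-2 beta2)`, `OR_CN = exp(beta1 + beta2)`.
#'
#' @param beta1 Coefficient of the sum term `A + B`.
#' @param beta2 Coefficient of the difference term `A - B`.
#' @return Named numeric vector `c(or_cn=, or_allele=)`.
#' @examples
#' transform_joint(log(1.2) + 0.5 * log(1.5), -0.5 * log(1.5)) # c(1.2, 1.5)
#' @export
transform_joint <- function(beta1, beta2) {
  c(or_cn = exp(beta1 + beta2), or_allele = exp(-2 * beta2))
}

#' Run all association strategies on one cohort
#'
#' @param cohort Cohort data frame; `allele_bi` is fitted only when a `call`
#'   column is present.
#' @param strategies Character vector of strategies to run.
#' @return Named list of `ascn_fit` objects.
#' @export
fit_all_strategies <- function(cohort,
                               strategies = c("cn", "allele_multi",
                                              "allele_bi", "joint",
                                              "codominant")) {
  strategies <- match.arg(strategies, several.ok = TRUE,
                          choices = c("cn", "allele_multi", "allele_bi",
                                      "joint", "codominant"))
  if (is.null(cohort$call)) strategies <- setdiff(strategies, "allele_bi")
  fns <- list(cn = fit_cn, allele_multi = fit_allele_multi,
              allele_bi = fit_allele_bi, joint = fit_joint,
              codominant = fit_codominant)
  stats::setNames(lapply(strategies, function(s) fns[[s]](cohort)), strategies)
}

#' Tidy a set of association fits into a result table
#'
#' @param fits List of `ascn_fit` objects (e.g. from [fit_all_strategies()]).
#' @return Data frame with one row per strategy: `strategy`, `n_used`, `df`,
#'   `lrt`, `p_value`, `converged`, and for the Joint fit `or_cn`,
#'   `or_allele`.
#' @export
fits_to_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(strategy = f$strategy, n_used = f$n_used, df = f$df,
               lrt = f$lrt, p_value = f$p_value, converged = f$converged,
               or_cn = f$or_cn %||% NA_real_,
               or_allele = f$or_allele %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
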