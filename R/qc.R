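#' Hardy-Weinberg equilibrium test on bi-allelic genotype counts
#'
#' For SNPs inside CNV regions the bi-allelic calls in controls routinely
#' depart from Hardy-Weinberg proportions (deleted copies masquerade as
#' homozygotes, duplicated ones as noise/missing), so an HWE check in
#' controls is a standard QC step. The default is the exact conditional test:
#' given the sample size and allele counts, the probability of each possible
#' heterozygote count is computed and the p-value is the total probability of
#' outcomes no more likely than the observed one. A chi-square (1 df) version
#' is available.
#'
#' @param calls Either a character vector of calls (`"AA"`, `"AB"`, `"BB"`;
#'   `"missing"`/`NA` entries are dropped) or a named numeric vector of counts
#'   `c(AA=, AB=, BB=)`.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return The p-value. Monomorphic input returns 1 with a warning.
#' @examples
#' hwe_test(c(AA = 25, AB = 50, BB = 25))
#' hwe_test(c(AA = 50, AB = 0, BB = 50)) # extreme departure
#' @export
hwe_test <- function(calls, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cnt <- genotype_counts(calls)
  n_aa <- cnt[["AA"]]; n_ab <- cnt[["AB"]]; n_bb <- cnt[["BB"]]
  n <- n_aa + n_ab + n_bb
  if (n == 0L) stop("no non-missing genotype calls")
  n_b <- 2L * n_bb + n_ab
  if (n_b == 0L || n_b == 2L * n) {
    warning("monomorphic SNP; HWE p-value set to 1")
    return(1)
  }
  if (method == "chisq") {
    p_b <- n_b / (2 * n)
    e <- n * c((1 - p_b)^2, 2 * p_b * (1 - p_b), p_b^2)
    x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  nr <- min(n_b, 2L * n - n_b) # rarer allele count
  hets <- seq.int(nr %% 2L, nr, by = 2L)
  # log P(n_AB = h | n, nr) = log [ n! / (n_hom_r! h! n_hom_c!) 2^h / C(2n, nr) ]
  logp <- lfactorial(n) - lfactorial((nr - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nr + hets) / 2) + hets * log(2) -
    (lchoose(2 * n, nr))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_ab)
  if (length(obs) != 1L) stop("heterozygote count inconsistent with allele count")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-10)]))
}

genotype_counts <- function(calls) {
  if (is.numeric(calls)) {
    if (!all(c("AA", "AB", "BB") %in% names(calls))) {
      stop("genotype counts must be named AA, AB, BB")
    }
    return(calls[c("AA", "AB", "BB")])
  }
  calls <- calls[!is.na(calls) & calls != "missing"]
  bad <- setdiff(unique(calls), c("AA", "AB", "BB"))
  if (length(bad)) stop("invalid genotype calls: ", paste(bad, collapse = ", "))
  c(AA = sum(calls == "AA"), AB = sum(calls == "AB"), BB = sum(calls == "BB"))
}

#' Fraction of missing bi-allelic genotype calls
#'
#' @param calls Character vector of calls; `"missing"` or `NA` counts as
#'   missing.
#' @return Fraction in \[0, 1\]. A 5% threshold is the usual exclusion
#'   boundary for the bi-allelic (SNP-only) analysis.
#' @examples
#' missing_rate(c("AA", "AB", "missing", NA))
#' @export
missing_rate <- function(calls) {
  if (length(calls) == 0L) stop("no calls supplied")
  mean(is.na(calls) | calls == "missing")
}
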