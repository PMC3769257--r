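#' Resolve the total copy number of a SNP in one sample from CNV calls
#'
#' A SNP takes the copy number of the CNV segment of that sample overlapping
#' its position (1-based inclusive coordinates on both sides, the PennCNV
#' convention: a SNP at `position == end` is inside the segment); positions
#' covered by no segment carry the normal two copies. CNV boundaries are
#' per-sample, so the copy number is resolved per (SNP, sample) pair, never
#' per region.
#'
#' @param chrom,position Vectors (recycled to common length) giving the SNP
#'   coordinates.
#' @param sample_id Vector of sample identifiers, same length.
#' @param calls CNV call data frame from [read_rawcnv()].
#' @return Integer vector of total copy numbers. Overlapping calls with
#'   conflicting copy numbers for one (sample, position) raise an error.
#' @examples
#' calls <- data.frame(sample_id = "s1", chrom = "chr22", start = 100L,
#'                     end = 200L, cn = 3L)
#' resolve_cn("chr22", c(150L, 250L), "s1", calls) # 3, 2
#' @export
resolve_cn <- function(chrom, position, sample_id, calls) {
  n <- max(length(chrom), length(position), length(sample_id))
  chrom <- rep_len(chrom, n)
  position <- rep_len(position, n)
  sample_id <- rep_len(sample_id, n)
  out <- rep.int(2L, n)
  if (is.null(calls) || nrow(calls) == 0L) return(out)
  for (i in seq_len(n)) {
    hit <- calls$sample_id == sample_id[i] & calls$chrom == chrom[i] &
      calls$start <= position[i] & calls$end >= position[i]
    cns <- unique(calls$cn[hit])
    if (length(cns) > 1L) {
      stop(sprintf("conflicting overlapping CNV calls for sample %s at %s:%d (cn = %s)",
                   sample_id[i], chrom[i], position[i],
                   paste(cns, collapse = ", ")))
    }
    if (length(cns) == 1L) out[i] <- cns
  }
  out
}

#' Assign the ASCN state from copy number and B-allele frequency
#'
#' Given the total copy number `cn` resolved from the CNV calls, the state is
#' the allele composition whose expected BAF (`b / cn` for `b` B alleles) is
#' nearest the observed BAF. For one copy this is the 0.5 rule (BAF below 0.5
#' gives `A`, above gives `B`); for two or more copies the same
#' nearest-expected-BAF binning applies, with bin boundaries at the midpoints
#' and boundary ties resolved toward the lower B count. Zero copies always
#' give `NULL` regardless of BAF.
#'
#' @param cn Integer vector of total copy numbers in 0..4.
#' @param baf Numeric vector of B-allele frequencies in \[0, 1\].
#' @return Character vector of ASCN state labels.
#' @examples
#' assign_ascn(1, 0.23) # "A"
#' assign_ascn(3, 0.30) # "AAB"
#' @export
assign_ascn <- function(cn, baf) {
  n <- max(length(cn), length(baf))
  cn <- rep_len(as.integer(cn), n)
  baf <- rep_len(baf, n)
  if (any(is.na(cn)) || any(cn < 0L | cn > 4L)) {
    stop("cn must be an integer in 0..4")
  }
  if (any(is.na(baf)) || any(baf < 0 | baf > 1)) {
    stop("baf must lie in [0, 1]")
  }
  # Nearest of the expected BAFs {0, 1/cn, ..., 1}; ceiling(x - 0.5) rounds
  # half-integers down, i.e. ties go to the lower B count.
  b <- ifelse(cn == 0L, 0L, pmin(pmax(ceiling(baf * cn - 0.5), 0L), cn))
  state_label(cn - b, b)
}

#' Per-SNP QC summary from resolved states and bi-allelic calls
#'
#' Computes, for every SNP, the quantities that drive the retention filters:
#' the minor allele frequency of the bi-allelic calls, whether the SNP
#' overlaps any CNV call, the frequency of samples with an abnormal
#' (non-two) resolved copy number, the missing-call rate, and the HWE exact
#' test p-value among controls.
#'
#' @param obs Data frame of per-(SNP, sample) observations with columns
#'   `snp_id`, `sample_id`, `cn`, `call`, and `phenotype` (1 = case /
#'   group 1, 0 = control / group 2).
#' @param in_cnv Optional named logical vector (by `snp_id`) saying whether
#'   each SNP overlaps a CNV call; default derives it as `any(cn != 2)`.
#' @return Data frame with one row per SNP: `snp_id`, `n`, `maf`, `in_cnv`,
#'   `abnormal_cn_freq`, `missing_rate`, `hwe_p_controls`.
#' @export
snp_qc_summary <- function(obs, in_cnv = NULL) {
  split_obs <- split(obs, obs$snp_id)
  do.call(rbind, lapply(names(split_obs), function(id) {
    o <- split_obs[[id]]
    nonmiss <- o$call[!is.na(o$call) & o$call != "missing"]
    nb <- sum(nonmiss == "AB") + 2L * sum(nonmiss == "BB")
    fb <- if (length(nonmiss)) nb / (2 * length(nonmiss)) else NA_real_
    ctrl_calls <- o$call[o$phenotype == 0L]
    hwe_p <- tryCatch(
      suppressWarnings(hwe_test(ctrl_calls)),
      error = function(e) NA_real_)
    data.frame(
      snp_id = id,
      n = nrow(o),
      maf = if (is.na(fb)) NA_real_ else min(fb, 1 - fb),
      in_cnv = if (!is.null(in_cnv)) isTRUE(in_cnv[[id]]) else any(o$cn != 2L),
      abnormal_cn_freq = mean(o$cn != 2L),
      missing_rate = missing_rate(o$call),
      hwe_p_controls = hwe_p,
      stringsAsFactors = FALSE
    )
  }))
}

#' Retention filters for SNPs in the CNV association analysis
#'
#' A SNP enters the ASCN-based analyses when its minor allele frequency is at
#' least `maf_min`, it lies in a CNV region, and the frequency of samples
#' with an abnormal (non-two) copy number is at least `abnormal_min`. The
#' bi-allelic (SNP-only) strategy additionally requires a missing-call rate
#' below `missing_max`.
#'
#' @param qc Per-SNP QC table from [snp_qc_summary()] (columns `snp_id`,
#'   `maf`, `in_cnv`, `abnormal_cn_freq`, `missing_rate`).
#' @param maf_min Minimum minor allele frequency, default 0.05.
#' @param abnormal_min Minimum abnormal-copy-number frequency, default 0.05.
#' @param missing_max Missing-rate bound for bi-allelic eligibility,
#'   default 0.05.
#' @return The QC table with added logical columns `retained` and
#'   `bi_eligible` (`retained` and missing rate below the bound).
#' @export
filter_snps <- function(qc, maf_min = 0.05, abnormal_min = 0.05,
                        missing_max = 0.05) {
  qc$retained <- !is.na(qc$maf) & qc$maf >= maf_min & qc$in_cnv &
    qc$abnormal_cn_freq >= abnormal_min
  qc$bi_eligible <- qc$retained & qc$missing_rate < missing_max
  qc
}

#' Effective number of independent tests (Li-Ji style) on copy numbers
#'
#' Copy numbers of SNPs inside one CNV region are strongly correlated, so a
#' Bonferroni correction by the raw SNP count is far too severe for the
#' copy-number trend strategy. The eigenvalues of the SNP x SNP correlation
#' matrix of copy numbers give an effective test count:
#' `Meff = sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#'
#' @param cn_matrix Numeric matrix, individuals in rows, SNPs in columns,
#'   entries the resolved total copy numbers. Constant columns are dropped
#'   with a warning.
#' @return List with `m_eff` (the raw sum), `m_eff_ceiling` (rounded up, the
#'   value to use in a Bonferroni correction), `eigenvalues` and
#'   `n_snps_used`.
#' @examples
#' m <- cbind(a = c(2, 1, 3, 2), b = c(2, 1, 3, 2)) # perfectly correlated
#' li_ji_effective_tests(m)$m_eff # 1
#' @export
li_ji_effective_tests <- function(cn_matrix) {
  cn_matrix <- as.matrix(cn_matrix)
  keep <- apply(cn_matrix, 2, function(x) stats::var(x) > 0)
  if (any(!keep)) {
    warning(sum(!keep), " constant copy-number column(s) dropped")
  }
  cn_matrix <- cn_matrix[, keep, drop = FALSE]
  if (ncol(cn_matrix) < 2L) {
    stop("need at least 2 SNPs with non-constant copy numbers")
  }
  lambda <- eigen(stats::cor(cn_matrix), symmetric = TRUE,
                  only.values = TRUE)$values
  # guard the floor() against eigenvalues a rounding error below an integer
  lambda <- round(pmax(lambda, 0), 10)
  m_eff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  list(m_eff = m_eff, m_eff_ceiling = as.integer(ceiling(m_eff - 1e-9)),
       eigenvalues = lambda, n_snps_used = ncol(cn_matrix))
}

#' Bonferroni significance flags
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests (or effective number of tests), at least 1.
#' @param alpha Family-wise significance level, default 0.05.
#' @return Logical vector: `p < alpha / m` (NA p-values give NA).
#' @export
bonferroni <- function(p, m, alpha = 0.05) {
  stopifnot(m >= 1)
  p < alpha / m
}

#' Two-group ASCN association analysis from CNV calls and BAF/genotype data
#'
#' The full real-data path: for every SNP, the total copy number of each
#' sample is resolved from its CNV calls, the ASCN state is assigned from the
#' copy number and the B-allele frequency, SNPs are filtered on MAF, CNV
#' overlap and abnormal-copy-number frequency, and the association strategies
#' are run comparing the two groups (group 1 is coded as case, group 2 as
#' control). Multiple testing is corrected per strategy: the Joint and
#' Allele (multi) strategies by the number of retained SNPs, the Allele (bi)
#' strategy by the number of bi-eligible SNPs (missing rate below 5%), and
#' the CN strategy by the effective number of independent tests from
#' [li_ji_effective_tests()] on the copy-number matrix.
#'
#' @param calls CNV call data frame from [read_rawcnv()].
#' @param snps SNP annotation data frame: `snp_id`, `chrom`, `position`.
#' @param baf Per-(SNP, sample) data frame: `snp_id`, `sample_id`, `baf`,
#'   `call`.
#' @param pheno Data frame `sample_id`, `group` with group values 1 and 2;
#'   group 1 is analysed as cases.
#' @param alpha Family-wise significance level, default 0.05.
#' @return Data frame with one row per SNP: QC columns, per-strategy p-values
#'   and odds ratios, and corrected significance flags (`sig_*`). The numbers
#'   of tests used per strategy are attached as attribute `n_tests`.
#' @export
ascn_association <- function(calls, snps, baf, pheno, alpha = 0.05) {
  stopifnot(all(c("snp_id", "chrom", "position") %in% names(snps)),
            all(c("snp_id", "sample_id", "baf", "call") %in% names(baf)),
            all(c("sample_id", "group") %in% names(pheno)))
  if (!all(sort(unique(pheno$group)) %in% c(1L, 2L))) {
    stop("pheno$group must contain the values 1 (case) and 2 (control)")
  }
  obs <- merge(baf, snps, by = "snp_id")
  obs <- merge(obs, pheno, by = "sample_id")
  obs$phenotype <- ifelse(obs$group == 1L, 1L, 0L)
  obs$cn <- resolve_cn(obs$chrom, obs$position, obs$sample_id, calls)
  obs$state <- assign_ascn(obs$cn, obs$baf)
  stp <- parse_state(obs$state)
  obs$a_count <- stp$a_count
  obs$b_count <- stp$b_count

  # A SNP is "in a CNV region" when any sample's call overlaps it.
  in_cnv <- vapply(split(obs$cn, obs$snp_id), function(x) any(x != 2L),
                   logical(1))
  qc <- filter_snps(snp_qc_summary(obs, in_cnv = in_cnv))

  retained <- qc$snp_id[qc$retained]
  bi_eligible <- qc$snp_id[qc$bi_eligible]

  res <- qc
  grp_n <- table(factor(obs$phenotype, levels = c(1L, 0L)),
                 obs$snp_id)
  res$n_case <- as.integer(grp_n["1", res$snp_id])
  res$n_control <- as.integer(grp_n["0", res$snp_id])
  strat_cols <- c("p_joint", "or_cn_joint", "or_allele_joint", "p_cn",
                  "or_cn", "p_allele_multi", "or_allele_multi",
                  "p_allele_bi", "or_allele_bi")
  res[strat_cols] <- NA_real_
  for (id in retained) {
    o <- obs[obs$snp_id == id, ]
    jt <- fit_joint(o)
    cnf <- fit_cn(o)
    am <- fit_allele_multi(o)
    res[res$snp_id == id, c("p_joint", "or_cn_joint", "or_allele_joint")] <-
      c(jt$p_value, jt$or_cn, jt$or_allele)
    res[res$snp_id == id, c("p_cn", "or_cn")] <-
      c(cnf$p_value, exp(cnf$coefficients[["cn"]]))
    res[res$snp_id == id, c("p_allele_multi", "or_allele_multi")] <-
      c(am$p_value, exp(am$coefficients[["b_count"]]))
    if (id %in% bi_eligible) {
      ab <- fit_allele_bi(o)
      res[res$snp_id == id, c("p_allele_bi", "or_allele_bi")] <-
        c(ab$p_value, exp(ab$coefficients[["b_count"]]))
    }
  }

  # Effective number of tests for the CN strategy.
  m_eff <- NA_integer_
  if (length(retained) >= 2L) {
    cn_wide <- stats::reshape(
      obs[obs$snp_id %in% retained, c("sample_id", "snp_id", "cn")],
      idvar = "sample_id", timevar = "snp_id", direction = "wide")
    cn_mat <- as.matrix(cn_wide[, -1, drop = FALSE])
    m_eff <- tryCatch(
      suppressWarnings(li_ji_effective_tests(cn_mat)$m_eff_ceiling),
      error = function(e) length(retained))
  } else if (length(retained) == 1L) {
    m_eff <- 1L
  }

  n_tests <- c(joint = length(retained), allele_multi = length(retained),
               allele_bi = length(bi_eligible), cn = m_eff)
  res$sig_joint <- bonferroni(res$p_joint, max(1L, n_tests[["joint"]]), alpha)
  res$sig_allele_multi <- bonferroni(res$p_allele_multi,
                                     max(1L, n_tests[["allele_multi"]]), alpha)
  res$sig_allele_bi <- bonferroni(res$p_allele_bi,
                                  max(1L, n_tests[["allele_bi"]]), alpha)
  res$sig_cn <- bonferroni(res$p_cn, max(1L, n_tests[["cn"]]), alpha)
  attr(res, "n_tests") <- n_tests
  res
}
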