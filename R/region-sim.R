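#' Simulate a synthetic two-group CNV region dataset
#'
#' Builds, entirely in code, the four input tables of the real-data path
#' ([ascn_association()]): PennCNV-style CNV calls, a SNP annotation table, a
#' per-(SNP, sample) BAF/genotype table and a phenotype table. One common CNV
#' region segregates identically in the two groups (so the copy-number signal
#' is null); a chosen subset of the SNPs inside the region differs between
#' the groups in B allele frequency, the rest are null. SNPs outside the
#' region are included to exercise the CNV-overlap filter.
#'
#' This is a synthetic stand-in for array data: BAFs are the ideal `b / cn`
#' values plus Gaussian noise, and bi-allelic calls are drawn from the call
#' probability table. It emulates the structure, not the noise physics, of a
#' real platform.
#'
#' @param n_group1,n_group2 Samples per group (group 1 is the case group).
#' @param f_norm,cnv_type Region CNV frequency structure, as in
#'   [scenario_spec()]; shared by both groups.
#' @param f_b_null B allele frequency of the null SNPs (both groups).
#' @param f_b_group1,f_b_group2 B allele frequencies of the associated SNPs
#'   in each group.
#' @param n_assoc_snps,n_null_snps Numbers of associated and null SNPs inside
#'   the region.
#' @param n_outside_snps SNPs outside any CNV call.
#' @param baf_sd Standard deviation of the BAF noise.
#' @param call_table Call probability table used to generate the bi-allelic
#'   calls.
#' @param seed Optional integer seed.
#' @return List with elements `calls`, `snps`, `baf`, `pheno`, and
#'   `truth` (data frame flagging which SNPs carry a real group difference).
#' @export
simulate_region_data <- function(n_group1 = 60L, n_group2 = 60L,
                                 f_norm = 0.7, cnv_type = "both",
                                 f_b_null = 0.3,
                                 f_b_group1 = 0.5, f_b_group2 = 0.2,
                                 n_assoc_snps = 3L, n_null_snps = 5L,
                                 n_outside_snps = 2L,
                                 baf_sd = 0.03,
                                 call_table = default_call_table(),
                                 seed = NULL) {
  validate_call_table(call_table)
  run_with_seed(seed, {
    n <- n_group1 + n_group2
    sample_id <- sprintf("sample_%03d", seq_len(n))
    group <- rep(c(1L, 2L), c(n_group1, n_group2))

    # Region-level CNV genotype: two chromosomes each carrying 0/1/2 copies;
    # the region copy number is shared by every SNP inside the region.
    q <- chromosome_frequencies(scenario_spec(f_norm, cnv_type, 0.5))
    chrom_copies <- matrix(sample(0:2, 2L * n, replace = TRUE, prob = q),
                           ncol = 2L)
    cn_region <- rowSums(chrom_copies)

    region_start <- 17000000L
    region_end <- 17100000L
    n_in <- n_assoc_snps + n_null_snps
    pos_in <- as.integer(seq(region_start + 1000L, region_end - 1000L,
                             length.out = n_in))
    pos_out <- as.integer(region_end + 50000L + seq_len(n_outside_snps) * 10000L)
    snps <- data.frame(
      snp_id = sprintf("snp_%02d", seq_len(n_in + n_outside_snps)),
      chrom = "chr22",
      position = c(pos_in, pos_out),
      stringsAsFactors = FALSE
    )
    assoc <- c(rep(TRUE, n_assoc_snps), rep(FALSE, n_null_snps),
               rep(FALSE, n_outside_snps))

    baf_rows <- lapply(seq_len(nrow(snps)), function(k) {
      inside <- snps$position[k] >= region_start & snps$position[k] <= region_end
      cn <- if (inside) cn_region else rep.int(2L, n)
      fb <- if (assoc[k]) ifelse(group == 1L, f_b_group1, f_b_group2)
            else rep.int(f_b_null, n)
      b <- stats::rbinom(n, cn, fb)
      state <- state_label(cn - b, b)
      exp_baf <- ifelse(cn > 0L, b / cn, 0.5)
      baf <- pmin(pmax(exp_baf + stats::rnorm(n, 0, baf_sd), 0), 1)
      calls <- colnames(call_table)
      call <- vapply(state, function(s) {
        calls[sample.int(4L, 1L, prob = call_table[s, ])]
      }, character(1), USE.NAMES = FALSE)
      data.frame(snp_id = snps$snp_id[k], sample_id = sample_id,
                 baf = round(baf, 4), call = call, stringsAsFactors = FALSE)
    })

    carriers <- which(cn_region != 2L)
    calls_df <- if (length(carriers)) {
      data.frame(
        sample_id = sample_id[carriers],
        chrom = "chr22",
        start = region_start,
        end = region_end,
        cn = as.integer(cn_region[carriers]),
        num_snps = n_in,
        length = region_end - region_start + 1L,
        state = ifelse(cn_region[carriers] < 2L, "2", "5"),
        start_snp = snps$snp_id[1L],
        end_snp = snps$snp_id[n_in],
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(sample_id = character(), chrom = character(),
                 start = integer(), end = integer(), cn = integer(),
                 num_snps = integer(), length = integer(),
                 state = character(), start_snp = character(),
                 end_snp = character(), stringsAsFactors = FALSE)
    }

    list(
      calls = calls_df,
      snps = snps,
      baf = do.call(rbind, baf_rows),
      pheno = data.frame(sample_id = sample_id, group = group,
                         stringsAsFactors = FALSE),
      truth = data.frame(snp_id = snps$snp_id, associated = assoc,
                         in_region = c(rep(TRUE, n_in),
                                       rep(FALSE, n_outside_snps)),
                         stringsAsFactors = FALSE)
    )
  })
}
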