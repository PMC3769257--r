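sample_rawcnv_lines <- c(
  "chr22:17000000-17100000 numsnp=10 length=100001 state2,cn=1 sample_001 startsnp=snp_01 endsnp=snp_10",
  "chr22:17000000-17100000 numsnp=10 length=100,001 state5,cn=3 sample_002 startsnp=snp_01 endsnp=snp_10",
  "chr3:1000-2000   numsnp=4  length=1001 state1,cn=0 sample_003 startsnp=rs1 endsnp=rs4"
)

test_that("rawcnv files parse, tolerate whitespace, and round-trip bit-exactly", {
  f <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines(sample_rawcnv_lines, f)
  calls <- read_rawcnv(f)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$cn, c(1L, 3L, 0L))
  expect_equal(calls$chrom, c("chr22", "chr22", "chr3"))
  expect_equal(calls$start, c(17000000L, 17000000L, 1000L))
  expect_equal(calls$end, c(17100000L, 17100000L, 2000L))
  expect_equal(calls$length, c(100001L, 100001L, 1001L))
  expect_equal(calls$sample_id, c("sample_001", "sample_002", "sample_003"))
  expect_equal(calls$start_snp, c("snp_01", "snp_01", "rs1"))

  # write/read round trip preserves all fields bit-exactly
  f2 <- withr::local_tempfile(fileext = ".rawcnv")
  write_rawcnv(calls, f2)
  expect_identical(read_rawcnv(f2), calls)
  # and the canonical text itself is stable under a second round trip
  f3 <- withr::local_tempfile(fileext = ".rawcnv")
  write_rawcnv(read_rawcnv(f2), f3)
  expect_identical(readLines(f2), readLines(f3))

  # empty file -> zero rows
  fe <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines(character(), fe)
  expect_equal(nrow(read_rawcnv(fe)), 0L)

  # malformed lines report the line number
  fb <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines(c(sample_rawcnv_lines[1], "chr22:5-1 numsnp=1 length=1 state2,cn=1 s startsnp=a endsnp=b"), fb)
  expect_error(read_rawcnv(fb), "line 2")
  fb2 <- withr::local_tempfile(fileext = ".rawcnv")
  writeLines("chr22:100-200 numsnp=1 length=101 state0,cn=2 s startsnp=a endsnp=b", fb2)
  expect_error(read_rawcnv(fb2), "cn must be")
})

test_that("resolve_cn applies 1-based inclusive overlap with default two copies", {
  calls <- data.frame(sample_id = c("s1", "s1", "s2"), chrom = "chr22",
                      start = c(100L, 500L, 100L), end = c(200L, 600L, 200L),
                      cn = c(3L, 1L, 0L), stringsAsFactors = FALSE)
  expect_equal(resolve_cn("chr22", 150L, "s1", calls), 3L)
  expect_equal(resolve_cn("chr22", 300L, "s1", calls), 2L)
  expect_equal(resolve_cn("chr22", 200L, "s1", calls), 3L) # boundary inclusive
  expect_equal(resolve_cn("chr22", 100L, "s2", calls), 0L)
  expect_equal(resolve_cn("chr22", 150L, "s3", calls), 2L) # unknown sample
  expect_equal(resolve_cn("chr1", 150L, "s1", calls), 2L)  # other chromosome
  expect_equal(resolve_cn("chr22", c(150L, 550L, 999L), "s1", calls),
               c(3L, 1L, 2L))
  # the empty call set resolves everything to two copies
  expect_equal(resolve_cn("chr22", c(1L, 2L), "s1", calls[0, ]), c(2L, 2L))
  # conflicting overlapping calls are an error
  conf <- rbind(calls, data.frame(sample_id = "s1", chrom = "chr22",
                                  start = 150L, end = 180L, cn = 4L))
  expect_error(resolve_cn("chr22", 160L, "s1", conf), "conflicting")
})

test_that("assign_ascn picks the nearest expected BAF with ties toward fewer B alleles", {
  expect_equal(assign_ascn(0, 0.9), "NULL")
  expect_equal(assign_ascn(1, 0.23), "A")
  expect_equal(assign_ascn(1, 0.77), "B")
  expect_equal(assign_ascn(1, 0.5), "A") # tie toward lower B count
  expect_equal(assign_ascn(2, c(0.1, 0.5, 0.9)), c("AA", "AB", "BB"))
  expect_equal(assign_ascn(2, 0.25), "AA") # midpoint tie at 0.25 -> lower b
  expect_equal(assign_ascn(3, 0.30), "AAB")
  expect_equal(assign_ascn(3, c(0.05, 0.45, 0.95)), c("AAA", "AAB", "BBB"))
  expect_equal(assign_ascn(4, c(0.1, 0.3, 0.55, 0.8, 0.99)),
               c("AAAA", "AAAB", "AABB", "ABBB", "BBBB"))
  expect_error(assign_ascn(5, 0.5), "cn must be")
  expect_error(assign_ascn(2, 1.2), "baf")

  # monotone in BAF at fixed copy number
  for (cn in 1:4) {
    b_counts <- parse_state(assign_ascn(cn, seq(0, 1, by = 0.01)))$b_count
    expect_false(is.unsorted(b_counts))
  }
})

test_that("SNP filters enforce MAF, CNV overlap, abnormal-CN and missing-rate rules", {
  qc <- data.frame(
    snp_id = c("low_maf", "no_cnv", "rare_cnv", "good", "messy"),
    maf = c(0.04, 0.30, 0.30, 0.30, 0.30),
    in_cnv = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    abnormal_cn_freq = c(0.10, 0.00, 0.04, 0.10, 0.10),
    missing_rate = c(0.0, 0.0, 0.0, 0.04, 0.06),
    stringsAsFactors = FALSE
  )
  out <- filter_snps(qc)
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$bi_eligible, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("the effective number of tests follows the eigenvalue rule", {
  set.seed(101)
  # exactly uncorrelated columns (Helmert contrasts): Meff equals the count
  m <- stats::contr.helmert(11)
  expect_equal(li_ji_effective_tests(m)$m_eff, ncol(m), tolerance = 1e-8)

  # a perfectly correlated pair collapses to one test
  x <- c(2, 1, 3, 2, 4)
  expect_equal(li_ji_effective_tests(cbind(a = x, b = x))$m_eff, 1)
  expect_equal(li_ji_effective_tests(cbind(a = x, b = 2 * x))$m_eff, 1)

  # random matrix: matches a direct spectral computation
  r <- matrix(sample(0:4, 60, replace = TRUE), ncol = 5)
  got <- li_ji_effective_tests(r)
  lambda <- eigen(cor(r))$values
  expect_equal(got$m_eff,
               sum(ifelse(lambda >= 1, 1, 0) + lambda - floor(lambda)),
               tolerance = 1e-8)
  expect_gte(got$m_eff, 1)
  expect_lte(got$m_eff, 5 + 1e-9)
  expect_equal(got$m_eff_ceiling, as.integer(ceiling(got$m_eff - 1e-9)))

  # constant columns are dropped with a warning
  expect_warning(li_ji_effective_tests(cbind(a = x, b = x, c = rep(2, 5))),
                 "constant")
  expect_error(suppressWarnings(
    li_ji_effective_tests(cbind(a = rep(2, 5), b = rep(3, 5)))), "at least 2")
})

test_that("Bonferroni flags use the per-strategy test counts", {
  expect_true(bonferroni(0.01, 1))
  expect_false(bonferroni(0.01, 136))
  expect_true(bonferroni(0.002, 16))
  expect_equal(bonferroni(c(1e-5, 0.02, NA), 136), c(TRUE, FALSE, NA))
})

test_that("the synthetic two-group region analysis flags the differing SNPs and only those", {
  dat <- simulate_region_data(n_group1 = 80, n_group2 = 80, seed = 202)
  expect_identical(simulate_region_data(n_group1 = 80, n_group2 = 80,
                                        seed = 202)$baf, dat$baf)

  # the rawcnv representation round-trips bit-exactly
  f <- withr::local_tempfile(fileext = ".rawcnv")
  write_rawcnv(dat$calls, f)
  expect_identical(read_rawcnv(f)[, names(dat$calls)], dat$calls)

  res <- ascn_association(dat$calls, dat$snps, dat$baf, dat$pheno)
  truth <- dat$truth

  # SNPs outside the region are filtered out of the analysis
  outside <- truth$snp_id[!truth$in_region]
  expect_true(all(!res$retained[res$snp_id %in% outside]))
  expect_true(all(is.na(res$p_joint[res$snp_id %in% outside])))

  # Joint flags every truly differing SNP after Bonferroni, no null SNP
  assoc_ids <- truth$snp_id[truth$associated]
  null_ids <- truth$snp_id[truth$in_region & !truth$associated]
  expect_true(all(res$sig_joint[res$snp_id %in% assoc_ids]))
  expect_true(all(!res$sig_joint[res$snp_id %in% null_ids]))

  # copy numbers are shared across the region, so the CN strategy sees no
  # group difference and the effective number of CN tests collapses to 1
  expect_equal(attr(res, "n_tests")[["cn"]], 1L)
  expect_true(all(res$p_cn[res$retained] > 0.05 / 2, na.rm = TRUE))
  expect_equal(attr(res, "n_tests")[["joint"]], sum(res$retained))

  # group sizes are reported per SNP
  expect_true(all(res$n_case == 80L & res$n_control == 80L))
})
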