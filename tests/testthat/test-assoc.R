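test_that("a cohort with identical case and control state counts gives LRT 0 and p 1", {
  co <- balanced_null_cohort()
  for (fit in list(fit_cn(co), fit_allele_multi(co), fit_joint(co),
                   fit_codominant(co))) {
    expect_true(fit$converged)
    expect_equal(fit$lrt, 0, tolerance = 1e-8)
    expect_equal(fit$p_value, 1, tolerance = 1e-6)
  }
  expect_equal(fit_joint(co)$df, 2L)
  expect_equal(fit_codominant(co)$df, 4L) # 5 observed states
})

test_that("degenerate covariates are returned flagged, not raised", {
  co <- add_state_counts(data.frame(
    individual_id = 1:20, phenotype = rep(c(1L, 0L), 10),
    state = rep(c("AA", "AB"), each = 10)))
  co$state <- "AA"; co <- add_state_counts(co)
  f <- fit_cn(co)
  expect_false(f$converged)
  expect_true(is.na(f$p_value))
  # joint needs non-collinear sum and difference: only A-homozygous states
  co2 <- add_state_counts(data.frame(
    individual_id = 1:30, phenotype = rep(c(1L, 0L), 15),
    state = rep(c("A", "AA", "AAA"), each = 10)))
  f2 <- fit_joint(co2)
  expect_false(f2$converged)
  # a single observed state is an error for the codominant model
  expect_error(fit_codominant(co), "at least 2")
})

test_that("complete separation is flagged with the p-value withheld", {
  co <- add_state_counts(data.frame(
    individual_id = 1:20,
    phenotype = rep(c(1L, 0L), each = 10),
    state = rep(c("AAA", "A"), each = 10)))
  f <- fit_cn(co)
  expect_false(f$converged)
  expect_true(f$separated)
  expect_true(is.na(f$p_value))
})

test_that("allele relabelling symmetries hold where the models are equivalent", {
  co <- simulate_cohort(scenario_spec(0.5, "both", 0.35),
                        risk_model(1.3, 1.4), 500, 500, seed = 71)
  sw <- swap_alleles(co)
  # the CN strategy is invariant under relabelling (covariate unchanged)
  expect_equal(fit_cn(sw)$p_value, fit_cn(co)$p_value, tolerance = 1e-8)
  # at fixed copy number the swapped allele covariate is an affine map of the
  # original, so the allele trend statistic is invariant and the coefficient
  # flips sign; with varying CN the two allele trends are different models
  co_null_cn <- simulate_cohort(scenario_spec(1.0, "both", 0.35),
                                risk_model(1, 1.4), 500, 500, seed = 72)
  f1 <- fit_allele_multi(co_null_cn)
  f2 <- fit_allele_multi(swap_alleles(co_null_cn))
  expect_equal(f2$lrt, f1$lrt, tolerance = 1e-8)
  expect_lt(f2$coefficients[["b_count"]] * f1$coefficients[["b_count"]], 0)
  expect_equal(abs(f2$coefficients[["b_count"]]),
               abs(f1$coefficients[["b_count"]]), tolerance = 1e-6)
  # the joint model spans the same space under the swap: statistic invariant
  expect_equal(fit_joint(sw)$lrt, fit_joint(co)$lrt, tolerance = 1e-8)
  # ... and the transformed allele odds ratio inverts
  expect_equal(fit_joint(sw)$or_allele, 1 / fit_joint(co)$or_allele,
               tolerance = 1e-6)
})

test_that("maximized log-likelihoods match a dense grid search on tiny cohorts", {
  set.seed(73)
  for (rep in 1:4) {
    states <- sample(ascn_states()$state, 8, replace = TRUE)
    pheno <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
    co <- add_state_counts(data.frame(individual_id = 1:8, phenotype = pheno,
                                      state = states))
    interior <- function(f) f$converged && max(abs(f$coefficients)) < 10
    f_cn <- fit_cn(co)
    if (interior(f_cn)) {
      expect_equal(f_cn$loglik_full, oracle_grid_loglik(co$cn, pheno),
                   tolerance = 1e-4)
    }
    f_am <- fit_allele_multi(co)
    if (interior(f_am)) {
      expect_equal(f_am$loglik_full, oracle_grid_loglik(co$b_count, pheno),
                   tolerance = 1e-4)
    }
    expect_equal(f_cn$loglik_null,
                 8 * (0.5 * log(0.5) + 0.5 * log(0.5)), tolerance = 1e-10)
  }
})

test_that("trend coefficients recover the simulated single effect", {
  spec <- scenario_spec(0.5, "both", 0.35)
  # with a pure copy-number effect the CN model is correctly specified:
  # the expected-score oracle equals log(1.5) and the estimate lands within 3 SE
  beta_inf <- oracle_expected_beta(spec, risk_model(1.5, 1), "cn")
  expect_equal(beta_inf, log(1.5), tolerance = 1e-4)
  co <- simulate_cohort(spec, risk_model(1.5, 1), 1000, 1000, seed = 74)
  f <- fit_cn(co)
  i_cn <- which(names(f$coefficients) == "cn")
  expect_lt(abs(f$coefficients[["cn"]] - beta_inf), 3 * f$se[i_cn])

  beta_inf_a <- oracle_expected_beta(spec, risk_model(1, 1.5), "b_count")
  expect_equal(beta_inf_a, log(1.5), tolerance = 1e-4)
  co2 <- simulate_cohort(spec, risk_model(1, 1.5), 1000, 1000, seed = 75)
  f2 <- fit_allele_multi(co2)
  i_b <- which(names(f2$coefficients) == "b_count")
  expect_lt(abs(f2$coefficients[["b_count"]] - beta_inf_a), 3 * f2$se[i_b])
})

test_that("single-effect trend fits are biased when the other effect is also present", {
  spec <- scenario_spec(0.5, "both", 0.35)
  risk <- risk_model(1.5, 1.5)
  # the marginal (expected-score) coefficients differ from the simulated
  # single-parameter values: each trend soaks up part of the other effect
  beta_cn_inf <- oracle_expected_beta(spec, risk, "cn")
  beta_b_inf <- oracle_expected_beta(spec, risk, "b_count")
  expect_gt(beta_cn_inf, log(1.5) + 0.01)
  expect_gt(beta_b_inf, log(1.5) + 0.01)
})

test_that("joint coefficient transformation inverts the sum/difference parameterization", {
  expect_equal(transform_joint(0, 0), c(or_cn = 1, or_allele = 1))
  expect_equal(transform_joint(log(1.2) + 0.5 * log(1.5), -0.5 * log(1.5)),
               c(or_cn = 1.2, or_allele = 1.5), tolerance = 1e-12)
  expect_equal(transform_joint(log(1.5), 0),
               c(or_cn = 1.5, or_allele = 1), tolerance = 1e-12)
  # substitution check on the linear predictor: for every state,
  # beta1 * S + beta2 * D == (cn - 2) log or_cn + b log or_allele + const
  or_cn <- 1.3; or_allele <- 1.7
  b1 <- log(or_cn) + 0.5 * log(or_allele)
  b2 <- -0.5 * log(or_allele)
  st <- ascn_states()
  lhs <- b1 * st$cn + b2 * (st$a_count - st$b_count)
  rhs <- (st$cn - 2) * log(or_cn) + st$b_count * log(or_allele) + 2 * log(or_cn)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("the joint fit recovers both odds ratios and always uses 2 df", {
  spec <- scenario_spec(0.5, "both", 0.35)
  f <- fit_joint(simulate_cohort(spec, risk_model(1.5, 1.5), 2000, 2000,
                                 seed = 76))
  expect_equal(f$df, 2L)
  expect_true(f$converged)
  expect_lt(abs(log(f$or_cn) - log(1.5)), 0.2)
  expect_lt(abs(log(f$or_allele) - log(1.5)), 0.2)
})

test_that("allele(bi) equals allele(multi) when all copies are 2 and no call is missing", {
  co <- simulate_cohort(scenario_spec(1.0, "both", 0.35),
                        risk_model(1, 1.4), 400, 400, seed = 77)
  co$call <- co$state # faithful calling at CN = 2
  fb <- fit_allele_bi(co)
  fm <- fit_allele_multi(co)
  expect_equal(fb$lrt, fm$lrt, tolerance = 1e-9)
  expect_equal(fb$p_value, fm$p_value, tolerance = 1e-9)
  expect_equal(fb$n_used, nrow(co))
})

test_that("allele(bi) uses only the non-missing subset", {
  co <- simulate_cohort(scenario_spec(0.5, "both", 0.35),
                        risk_model(1, 1), 200, 200, seed = 78)
  tab <- default_call_table()
  # make every abnormal-CN call missing
  st <- ascn_states()
  for (s in st$state[st$cn != 2]) tab[s, ] <- c(0, 0, 0, 1)
  co <- degrade_to_genotypes(co, tab, seed = 79)
  f <- fit_allele_bi(co)
  expect_equal(f$n_used, sum(co$call != "missing"))
  expect_equal(f$n_used, sum(co$cn == 2 & co$call != "missing"))
  co$call <- "missing"
  expect_error(fit_allele_bi(co), "missing")
})

test_that("allele(bi) loses the copy-number signal that allele(multi) detects", {
  # a pure copy-number effect with both deletions and duplications: the
  # bi-allelic strategy rejects far less often than the multi-allelic one
  spec <- scenario_spec(0.5, "both", 0.35)
  risk <- risk_model(1.5, 1)
  n_reps <- 60
  rej <- matrix(0, n_reps, 2)
  for (r in seq_len(n_reps)) {
    co <- simulate_cohort(spec, risk, 1000, 1000, seed = 2000 + r)
    co <- degrade_to_genotypes(co, seed = 3000 + r)
    rej[r, 1] <- fit_allele_multi(co)$p_value < 0.05
    rej[r, 2] <- fit_allele_bi(co)$p_value < 0.05
  }
  expect_gt(mean(rej[, 1]), 0.9)
  expect_lt(mean(rej[, 2]), mean(rej[, 1]) - 0.3)
})

test_that("fits_to_table flattens a strategy set", {
  co <- simulate_cohort(scenario_spec(0.5, "both", 0.2),
                        risk_model(1.2, 1.2), 300, 300, seed = 80)
  co <- degrade_to_genotypes(co, seed = 81)
  tab <- fits_to_table(fit_all_strategies(co))
  expect_setequal(tab$strategy,
                  c("cn", "allele_multi", "allele_bi", "joint", "codominant"))
  expect_true(all(tab$lrt >= 0, na.rm = TRUE))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_false(is.na(tab$or_cn[tab$strategy == "joint"]))
})

test_that("the exact HWE test matches full enumeration and handles edge cases", {
  expect_gt(hwe_test(c(AA = 25, AB = 50, BB = 25)), 0.5)
  expect_lt(hwe_test(c(AA = 50, AB = 0, BB = 50)), 1e-10)
  expect_warning(p <- hwe_test(c(AA = 30, AB = 0, BB = 0)), "monomorphic")
  expect_equal(p, 1)

  set.seed(82)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    nab <- sample(0:n, 1)
    naa <- sample(0:(n - nab), 1)
    nbb <- n - nab - naa
    if (2 * nbb + nab == 0 || 2 * naa + nab == 0) next
    expect_equal(hwe_test(c(AA = naa, AB = nab, BB = nbb)),
                 oracle_hwe_exact(naa, nab, nbb), tolerance = 1e-9,
                 label = sprintf("exact HWE at (%d, %d, %d)", naa, nab, nbb))
  }
  # the chi-square variant agrees with base R's test
  cs <- hwe_test(c(AA = 40, AB = 80, BB = 60), method = "chisq")
  n <- 180; pb <- (2 * 60 + 80) / (2 * n)
  e <- n * c((1 - pb)^2, 2 * pb * (1 - pb), pb^2)
  x2 <- sum((c(40, 80, 60) - e)^2 / e)
  expect_equal(cs, pchisq(x2, 1, lower.tail = FALSE))
  # call vectors work too
  expect_equal(hwe_test(rep(c("AA", "AB", "BB"), c(25, 50, 25))),
               hwe_test(c(AA = 25, AB = 50, BB = 25)))
})

test_that("missing_rate counts 'missing' and NA entries", {
  expect_equal(missing_rate(c("AA", "AB", "BB")), 0)
  expect_equal(missing_rate(rep("missing", 4)), 1)
  expect_equal(missing_rate(c(rep("AA", 95), rep("missing", 5))), 0.05)
  expect_equal(missing_rate(c("AA", NA)), 0.5)
})
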