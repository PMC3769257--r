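# Independent oracles used across the suite. Each restates the model from
# first principles (enumeration, brute-force simulation, grid search) without
# going through the package's analytic code paths.

# Chromosome frequencies restated from the scenario definition.
oracle_chrom_freqs <- function(f_norm, cnv_type) {
  rest <- 1 - f_norm
  switch(cnv_type,
         del = c(rest, f_norm, 0),
         dup = c(0, f_norm, rest),
         both = c(rest / 2, f_norm, rest / 2))
}

# Monte-Carlo oracle for the control state distribution: draw two chromosomes
# carrying 0/1/2 copies, then independent allele draws per copy.
oracle_mc_state_freqs <- function(f_norm, cnv_type, f_b, n_draws = 1e6) {
  q <- oracle_chrom_freqs(f_norm, cnv_type)
  cn <- sample(0:2, n_draws, replace = TRUE, prob = q) +
    sample(0:2, n_draws, replace = TRUE, prob = q)
  b <- rbinom(n_draws, cn, f_b)
  labs <- ifelse(cn == 0, "NULL",
                 paste0(strrep("A", cn - b), strrep("B", b)))
  counts <- table(factor(labs, levels = ascn_states()$state))
  as.numeric(counts) / n_draws
}

# Exact enumeration oracle for the copy-number distribution: all 9 ordered
# chromosome pairs.
oracle_cn_distribution <- function(f_norm, cnv_type) {
  q <- oracle_chrom_freqs(f_norm, cnv_type)
  p <- numeric(5)
  for (i in 0:2) for (j in 0:2) p[i + j + 1] <- p[i + j + 1] + q[i + 1] * q[j + 1]
  p
}

# Dense grid-search oracle for the maximized Bernoulli log-likelihood of a
# 1-covariate logistic model on a tiny cohort.
oracle_grid_loglik <- function(x, pheno) {
  ll <- function(a, b) {
    eta <- a + b * x
    sum(pheno * eta - log1p(exp(eta)))
  }
  best <- c(0, 0)
  for (step in c(0.8, 0.04, 0.002)) {
    alphas <- best[1] + seq(-20 * step, 20 * step, by = step)
    betas <- best[2] + seq(-20 * step, 20 * step, by = step)
    vals <- outer(alphas, betas, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    best <- c(alphas[k[1]], betas[k[2]])
  }
  ll(best[1], best[2])
}

# Exact HWE oracle by direct enumeration: conditional probability of each
# heterozygote count given sample size and allele counts, via choose().
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nb <- 2 * n_bb + n_ab
  nr <- min(nb, 2 * n - nb)
  hets <- seq(nr %% 2, nr, by = 2)
  prob <- sapply(hets, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- n - hom_r - h
    factorial(n) / (factorial(hom_r) * factorial(h) * factorial(hom_c)) *
      2^h / choose(2 * n, nr)
  })
  p_obs <- prob[hets == n_ab]
  sum(prob[prob <= p_obs * (1 + 1e-10)])
}

# Expected-score oracle: the logistic coefficient a strategy converges to at
# infinite sample size, obtained by maximizing the expected log-likelihood
# over the analytic case/control state distributions.
oracle_expected_beta <- function(spec, risk, covariate = c("cn", "b_count"),
                                 case_fraction = 0.5) {
  covariate <- match.arg(covariate)
  st <- ascn_states()
  x <- if (covariate == "cn") st$cn else st$b_count
  pc <- case_state_frequencies(control_state_frequencies(spec), risk)
  p0 <- control_state_frequencies(spec)
  negll <- function(par) {
    eta <- par[1] + par[2] * x
    -sum(case_fraction * pc * (eta - log1p(exp(eta))) +
           (1 - case_fraction) * p0 * (-log1p(exp(eta))))
  }
  optim(c(0, 0), negll, method = "BFGS")$par[2]
}

# Small deterministic cohorts used by several tests.
balanced_null_cohort <- function() {
  states <- c("AA", "AB", "BB", "A", "ABB")
  data.frame(
    individual_id = seq_len(2 * length(states) * 10),
    phenotype = rep(c(1L, 0L), each = length(states) * 10),
    state = rep(rep(states, each = 10), 2),
    stringsAsFactors = FALSE
  ) |> add_state_counts()
}

add_state_counts <- function(cohort) {
  st <- parse_state(cohort$state)
  cohort$a_count <- st$a_count
  cohort$b_count <- st$b_count
  cohort$cn <- st$cn
  cohort
}

swap_alleles <- function(cohort) {
  cohort$state <- state_label(cohort$b_count, cohort$a_count)
  tmp <- cohort$a_count
  cohort$a_count <- cohort$b_count
  cohort$b_count <- tmp
  cohort
}
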