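---
title: "Association testing for SNPs inside common CNVs with allele-specific copy number states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association testing for SNPs inside common CNVs with allele-specific copy number states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascnassoc)
```

## The problem

A SNP located inside a common copy number variant is not carried on exactly
two chromosomal copies. With region copy numbers from 0 to 4 and two alleles
A and B, an individual carries one of 15 *allele-specific copy number* (ASCN)
states — the unordered multiset of alleles: `NULL` (zero copies), `A`, `B`,
`AA`, `AB`, `BB`, `AAA`, `AAB`, ..., `BBBB`. A standard SNP caller, which
assumes two copies everywhere, collapses these states into `AA`/`AB`/`BB`
or `missing`. Two things then go wrong in a case-control association scan:

* the copy-number part of the signal is discarded, and part of the allelic
  signal is distorted (a deleted `B` hemizygote looks like `BB`, a duplicated
  state is mostly missing);
* the SNP tends to fail standard QC (high missingness, Hardy-Weinberg
  departure in controls) and is dropped before any test is run.

This package implements and evaluates association strategies that work on
the ASCN states directly.

## Population model

Each individual carries two region haplotypes, each bearing 0 (deleted), 1
(normal) or 2 (duplicated) copies. A frequency scenario is parameterized by
the normal-chromosome frequency `f_norm`, the CNV type, and the B allele
frequency `f_b`:

* one CNV type only: the variant chromosome has frequency `1 - f_norm`;
* deletions and duplications together: `f_del = f_dup = (1 - f_norm) / 2`.

The total copy number is the sum over the chromosome pair, and conditional
on `cn` copies the number of B alleles is binomial `(cn, f_b)` — each copy
draws its allele independently, including the two copies of a duplicated
chromosome. (Whether those two copies should share one draw is a genuinely
open modelling choice; independent draws are the simplest assumption
consistent with combining per-copy allele frequencies, and they are what the
generator uses throughout.) `control_state_frequencies()` returns the
resulting 15-state distribution; a Monte-Carlo oracle that literally draws
chromosome pairs confirms it in the test suite.

Disease risk is multiplicative in both coordinates with `AA` as reference:

RR(state) = RR_CN^(cn - 2) * RR_allele^(b_count).

Case-state frequencies follow by reweighting the control distribution with
these relative risks and renormalizing. Under case-control sampling this
construction makes the per-state odds ratio versus `AA` exactly equal to
RR(state), which is what lets the Joint model recover the simulated effects
without bias (below).

The `NULL` state deserves a note: it has no alleles, and the multiplicative
formula applied at `cn = 0` gives it RR_CN^(-2). That is a modelling
convention, not a biological statement — a two-copy deletion might well
carry a different risk. `risk_model(..., null_state_rr = )` overrides it.

The study grid is the Cartesian product `f_norm` in {0.8, 0.5, 1/3} x three
CNV types x `f_b` in {0.05, 0.20, 0.35, 0.50} (36 frequency scenarios) and
`RR_CN`, `RR_allele` in {1, 1.2, 1.5, 2} (16 risk settings including the
global null).

## The five strategies

All are logistic regressions of case status tested against the
intercept-only model with a likelihood-ratio test:

| strategy | covariate(s) | df | data used |
|---|---|---|---|
| `fit_cn()` | total copies `A + B` | 1 | ASCN states |
| `fit_allele_bi()` | B count in the bi-allelic call | 1 | calls, missing excluded |
| `fit_allele_multi()` | B count in the ASCN state | 1 | ASCN states |
| `fit_joint()` | sum `A + B` and difference `A - B` | 2 | ASCN states |
| `fit_codominant()` | one indicator per observed state | #states - 1 | ASCN states |

The Joint model's raw coefficients do not estimate the two effects directly.
Substituting `cn = S` and `b = (S - D) / 2` into the risk linear predictor
shows that the sum coefficient equals `log RR_CN + log(RR_allele) / 2` (the
copy-number effect plus half the allele effect) and the difference
coefficient equals `-log(RR_allele) / 2`. `transform_joint()` inverts this:
`OR_allele = exp(-2 b2)`, `OR_CN = exp(b1 + b2)`. Medians of the transformed
odds ratios across replicates recover the simulated relative risks; the
single-covariate `CN` and `Allele (multi)` coefficients are marginal
estimates and are biased upward whenever both effects are present (the test
suite checks the direction against an expected-score oracle that maximizes
the expected log-likelihood over the analytic state distribution).

```{r joint-example}
spec <- scenario_spec(f_norm = 0.5, cnv_type = "both", f_b = 0.35)
co <- simulate_cohort(spec, risk_model(rr_cn = 1.5, rr_allele = 1.5),
                      n_cases = 1000, n_controls = 1000, seed = 1)
fit_joint(co)
```

Numerical conventions for the fits:

* individuals sharing a covariate pattern are pooled, so each fit is a small
  weighted binomial regression (15 rows at most); reported log-likelihoods
  are the per-individual Bernoulli ones and LRT statistics are identical to
  the ungrouped fit, at a fraction of the cost;
* a constant or collinear covariate (e.g. every individual at two copies, or
  only A-homozygous states so that `A - B` duplicates `A + B`) returns a fit
  flagged `converged = FALSE` with the p-value withheld, rather than an
  error — the study engine counts such replicates as failed instead of
  crashing a scan;
* complete separation (every covariate group phenotype-pure and saturated)
  is likewise flagged; partial saturation, such as one empty cell of a rare
  codominant state, is *not* treated as failure — those replicates carry real
  information and excluding them would understate the codominant model's
  small-sample inflation;
* p-values come from the asymptotic chi-square at the stated df, with no
  small-sample correction;
* when `AA` is absent from a cohort the codominant reference falls back to
  the most frequent observed state and the fit is annotated.

## Degradation to bi-allelic calls

`degrade_to_genotypes()` maps each state to `AA`/`AB`/`BB`/`missing` with the
probabilities of a per-state call table. The packaged default
(`default_call_table()`, also shipped as
`inst/extdata/default_call_table.tsv`) encodes the qualitative behaviour of
two-copy callers: one- and two-copy states call faithfully with a 0.5%
missing rate; zero-, three- and four-copy states are 60-85% missing with the
rest on compatible calls; heterozygous three- and four-copy states get
deliberately asymmetric missing rates (`AAB` vs `ABB`, `AAAB` vs `ABBB`),
mimicking the dye bias of real arrays. These numbers are a synthetic,
documented default — not estimates from any specific platform. Anyone with
matched ASCN/call data should calibrate their own table and pass it in; all
downstream code takes the table as an argument.

## CNV calling errors

`inject_errors()` models imperfect CNV detection with a sensitivity
(default studies use 0.2 or 0.5) and a specificity (0.99):

* a missed carrier (probability `1 - sensitivity`) collapses to a two-copy
  state — `AA`/`BB` if homozygous, `AB` if heterozygous, uniform over the
  three genotypes for `NULL`;
* a falsely flagged two-copy individual (probability `1 - specificity`)
  receives a wrong copy number uniform on {0, 1, 3, 4} and a state remap
  preserving allele content (`AA -> A/AAA/AAAA`; `AB -> {A,B}`,
  `{AAB, ABB}`, `{AAAB, AABB, ABBB}`; wrong 0 -> `NULL`).

Where the error model lists outcomes without weights, every such choice is
uniform — one convention applied to all branches.

## The study engine

`run_study()` scans (scenario x risk) cells, simulating cohorts and fitting
strategies per replicate; power is the fraction of converged replicates with
p below the significance level (0.05 by default), with the Monte-Carlo
standard error `sqrt(p(1-p)/reps)` attached. Failed replicates are counted
and reported, never silently dropped; power denominators use the converged
count. One master seed derives a substream seed per replicate, so results
are bit-reproducible and independent of evaluation order or any future
parallelization of the cell loop.

Scales used by this package's own checks (chosen to keep a full run on one
CPU in minutes): type-I calibration and the codominant-inflation scan at
10,000 replicates per cell; power curves, relative-power scans and
estimator-recovery checks at 1,000 replicates per cell; 1,000 cases and
1,000 controls throughout. The full published-style design (10,000
replicates on every one of the 36 x 16 cells, plus a 5,000/5,000 sample-size
arm) uses the same code with a larger `study_config()`.

Two findings worth restating as caveats:

* the codominant model's type-I error inflates (to roughly 7-8% at nominal
  5%) in null scenarios with low-frequency duplications, where some state
  cells hold a handful of individuals against 14 degrees of freedom;
* the bi-allelic allele trend can flag a *protective* B effect when only a
  copy-number effect is simulated (deletions make `B` hemizygotes look like
  `BB`). Power here is always the two-sided fraction of p < 0.05, so such
  artefactual rejections count toward the Allele (bi) "power" even though
  the effect estimate points the wrong way — a reason to read that
  strategy's power column together with its odds ratios.

## Real-data path

`ascn_association()` goes from PennCNV `.rawcnv` calls, a SNP annotation
table, per-(SNP, sample) BAF and genotype calls, and a two-group phenotype
table to per-SNP results:

1. per (SNP, sample), the total copy number is the `cn` of the overlapping
   call segment (1-based inclusive coordinates on both ends, the PennCNV
   convention) or 2 when none overlaps; conflicting overlapping segments
   raise an error rather than being resolved silently — boundaries are
   per-sample, so `cn` is never resolved per region;
2. `assign_ascn()` picks the state whose expected BAF (`b / cn`) is nearest
   the observed BAF. Only the one-copy rule (BAF below/above 0.5 gives
   `A`/`B`) is classical; for two or more copies "most probable state" is
   not standardized, so nearest-expected-BAF with midpoint boundaries is
   used, ties resolved toward the lower B count. The bins are a documented
   stand-in, and monotonicity of the B count in BAF is tested;
3. SNPs are kept when MAF >= 0.05, they lie in a CNV region, and at least 5%
   of samples have an abnormal copy number; the bi-allelic strategy
   additionally requires under 5% missing calls;
4. group 1 is coded as case, group 2 as control;
5. Bonferroni corrections use each strategy's own test count; the CN
   strategy alone uses the effective number of independent tests
   (`li_ji_effective_tests()`: eigenvalues of the SNP x SNP copy-number
   correlation matrix, `sum(1(lambda >= 1) + frac(lambda))`, rounded up),
   because copy numbers of SNPs in one region are nearly perfectly
   correlated. Eigenvalues are rounded at the tenth decimal before taking
   `floor()` — an eigenvalue of exactly 2 computed as `2 - 1e-15` would
   otherwise contribute a spurious unit.

`simulate_region_data()` builds a fully synthetic two-group fixture for this
path (one region whose CNV structure is identical across groups, some SNPs
with a real allele-frequency difference, null SNPs, SNPs outside the
region). It emulates the *structure* of array data — region-wide copy
numbers, BAF as `b/cn` plus Gaussian noise, calls drawn from the call
table — not intensity physics, batch effects or per-sample quality drift; a
pass on this fixture validates the plumbing and the statistics, not any
particular array platform.

## Limitations

* States are phase-free by construction: a given state carries one risk no
  matter how its alleles split across the two chromosomes. Phase-aware risk
  models are out of scope.
* Copy numbers above 4 and multi-allelic SNPs are not represented.
* No covariate adjustment (age, sex, ancestry) in the logistic models.
* The default call table and the BAF binning rules are documented synthetic
  stand-ins, to be calibrated per platform.
* CNV calling itself (intensity segmentation) is upstream of this package.
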