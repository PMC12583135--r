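---
title: "Estimating heritability and household effects from proband-reported extended families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heritability and household effects from proband-reported extended families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedherit)
```

## The problem

Family-history registries ask one participant (the proband) to report the
structure of their extended family and which relatives had which brain
diseases, at what age.  From many such families one can partition the
variance of a disease trait into an additive genetic part, a part shared by
all members of a family (the household), and an individual residual - the
familiar (h², c², e²) decomposition - without genotyping anyone.  pedherit
implements that pipeline: pedigree kinship, phenotype preparation,
variance-components maximum likelihood, a family-level bootstrap, and
multi-disease reporting, together with a liability-threshold simulator that
makes every stage testable against known truth.

## The model

For a family *f* with trait vector \(y_f\) and covariates \(X_f\), the
model is Gaussian with

\[
\Omega_f \;=\; 2\Phi_f\,\sigma_g^2 \;+\; H_f\,\sigma_c^2 \;+\; I\,\sigma_e^2 ,
\]

where \(\Phi_f\) is the kinship matrix computed by the classical recursion
(parent-child and full siblings share 50% of their genetic factors,
grandparent-grandchild and half-siblings 25%, unrelated partners 0%), and
\(H_f\) is an all-ones matrix: every family is taken to share one
household, with no finer nesting.  Families are independent, so the
log-likelihood is a sum of per-family multivariate-normal terms; each term
is evaluated through a per-family Cholesky factorisation and no
cohort-sized matrix is ever assembled, so memory scales with the largest
family.

Fixed effects are an intercept, sex, age, age², age × sex and age² × sex.
Age is determined per disease with the precedence *onset, then assessment,
then death*, and is centred at the included-sample mean before squaring;
centring affects numerical conditioning only, not the fitted model space.
Rank-deficient designs (a single-sex subsample, for instance) drop the
offending columns with a warning instead of failing.

Binary disease status is fitted on the observed 0/1 scale under this
Gaussian likelihood.  A full multivariate-probit threshold model is out of
scope; the classical observed-to-liability conversion
(`liability_scale_transform()`, multiplier \(K(1-K)/\varphi(z)^2\)) is
available as an interpretation aid and is off by default.

### Fitting

The fixed effects have a closed-form GLS solution at any variance value,
and so does the total variance; both are profiled out, leaving a 1- or
2-dimensional optimisation over the variance *proportions* (h², c²) on the
unit simplex.  That parameterisation enforces non-negativity without
penalties.  The profile is maximised from three deterministic restarts
(h² = 0.1, 0.5, 0.9) plus explicit boundary profiles (h² = 0, c² = 0, and
the origin), with ties broken toward the smaller genetic proportion.
Convergence is declared at a relative log-likelihood change below 1e-8
within 500 iterations; a fit that stalls is reported with
`converged = FALSE`, never as an exception.

Because a variance component's null value lies on the boundary of its
parameter space, the likelihood-ratio statistic against \(\sigma_g^2 = 0\)
(or \(\sigma_c^2 = 0\)) is referred to the mixture
\(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\).  Simulation under the null
reproduces the nominal type-I error (about half of null fits land exactly
on the boundary).  When all individuals are unrelated and no household is
fitted, \(\sigma_g^2\) and \(\sigma_e^2\) are not separately identifiable;
the fitter probes the profile likelihood and flags the near-flat case
(`identifiable = FALSE`) rather than reporting a confident h².

The household component is only fitted for diseases with at least 225
cases (configurable, with a manual override); below that count such models
lack the power to converge and the fit is refused with a classed error so
the caller can retry without the household term.

### Bootstrap

Sampling variability is assessed by a cluster bootstrap: whole families
are drawn with replacement, and a duplicated family enters the likelihood
as an independent copy (standard cluster-bootstrap semantics; reweighting
was rejected as it changes the resampling distribution).  Each replicate's
multiset is a pure function of `(seed, replicate_index)`, so any replicate
is reproducible in isolation.  The reported point estimate is the
bootstrap mean (the median is also kept), and the interval is the
2.5-97.5 percentile range of successful replicates; replicates that fail
to converge are counted and excluded, and the run aborts once failures
exceed a budget.  Registry-scale defaults are 3000 replicates of 2000
families (reduced per-replicate counts, e.g. 1000 families, are advisable
for very prevalent traits, and household-free robustness passes typically
use 1000 replicates across all families).

The *shape* of the bootstrap distribution is a diagnostic of genetic
architecture: a polygenic trait gives approximately normal estimates,
while a mixture of sporadic cases and rare autosomal-dominant families
gives skewed or bimodal ones.  `summarize_distribution()` combines a
Shapiro-Wilk test (not normal when p < 0.01) with the sample bimodality
coefficient \((g_1^2+1)/(g_2 + 3(n-1)^2/((n-2)(n-3)))\), calling a
non-normal distribution bimodal above the uniform-distribution benchmark
0.555 and skewed otherwise.  These fixed thresholds are deliberate: the
labels are meant as coarse, reproducible flags, not as a model of the
estimate distribution.

### Multiple testing

P-values are adjusted across diseases by the Benjamini-Hochberg step-up
procedure.  The h² tests and the c² tests are adjusted as two separate
families by default (they answer different questions and the c² family is
smaller because rare diseases carry no household term); pooled adjustment
is available by configuration.

## The simulator

`simulate_cohort()` generates proband-style extended families with a known
variance structure, so that recovery, calibration and coverage can be
checked against truth:

* **Structure.**  Each family starts from a founding couple; children
  partner with probability 0.75, re-partner with probability 0.08
  (producing half-sibships), and have a Poisson(2.5) number of children;
  the founding couple always has at least one child so every family spans
  two generations.  Defaults give three generations and a mean family size
  near 11.9.
* **Demographics.**  Generations are spaced 28 years apart with the
  youngest adult generation at about age 62 at assessment, and vital
  status follows a normal lifespan model (mean 78, SD 12), so roughly half
  of a three-generation cohort is deceased - echoing the age and mortality
  mix of proband-reported registries without attempting demographic
  realism.
* **Liability.**  Per disease, liability = fixed effects (sex, age) +
  additive genetic value + household effect + residual.  Additive values
  are gene-dropped: founders drawn with variance \(\sigma_g^2\), offspring
  as the mid-parent value plus a Mendelian-sampling deviate of variance
  \(\sigma_g^2/2\), which preserves the additive variance in every
  generation.  The affection threshold is the empirical liability quantile
  matching the target prevalence, so realised prevalence tracks the target
  by construction.
* **Onset.**  Age at onset is `onset_mean - k (liability - threshold) +
  noise`, truncated to the individual's attained age, with k = 5
  years per liability unit by default: a deliberately simple monotone link
  (higher liability, earlier onset) sufficient to exercise the
  age-precedence logic; the registries report only marginal onset means
  and SDs, not an onset mechanism.
* **Monogenic families.**  A configurable fraction of families carries a
  fully dominant risk allele dropped from one founder (children of a
  carrier inherit with probability 1/2); carriers become affected with the
  configured penetrance, overriding their polygenic status.  This emulates
  the sporadic/autosomal-dominant mixture that makes bootstrap h²
  distributions depart from normality for rare diseases.

What the simulator does **not** emulate: volunteer ascertainment (families
are drawn unconditionally; registry self-selection is unquantifiable from
summary data), reporting error and misdiagnosis in proxy reports,
possible duplication of the same family reported by two probands,
assortative mating, maternal effects, X-linked or mitochondrial
transmission, and realistic fertility/mortality schedules.  Passing the
validation suite therefore demonstrates correctness of the estimation
machinery under the stated model, not robustness to those real-data
complications.

## Numerical and design choices

* Kinship supports inbreeding (the diagonal of 2Φ may exceed 1) even
  though simulated cohorts are non-inbred - the general recursion is cheap
  and testable.  An individual with a single known parent treats the
  unknown parent as a unique founder.
* Family deduplication is not implemented (reports of the same family by
  different probands cannot be distinguished at this level); this mirrors
  a stated limitation of registry data.
* The early-onset exclusion (dementia before 20, stroke before 10, by
  default) removes the person from *that disease's* analysis rather than
  recoding them unaffected; recoding is available by configuration since
  the registry convention is ambiguous.  Rare diseases are dropped at
  "50 cases or fewer", strictly.
* \(\sigma_e^2\) is kept strictly positive (proportion floor 1e-6) so the
  likelihood stays proper; residual sums of squares are floored at 1e-12.
* Proband and proxy reports are treated identically.

## Problem sizes used in the validation suite

The package's own validation runs at deliberately modest scale: kinship
oracles use 100,000 gene drops on a 12-member four-generation fixture;
parameter recovery uses 20 cohorts of 500 families; type-I calibration
uses 200 null fits on cohorts of about 2,000 individuals; bootstrap
coverage uses 200 replicates of 100 families; and the architecture
diagnostic contrasts a common polygenic disease (prevalence 8%) with a
rare disease (prevalence 0.5%) in which 15% of families carry a fully
penetrant dominant allele.  These sizes give stable Monte-Carlo behaviour
while keeping the full suite to a few minutes; registry-scale presets
remain available through the configuration objects.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_families = 400, seed = 90)
co <- simulate_cohort(cfg)
res <- run_study(co,
                 boot_config = bootstrap_config(n_replicates = 200,
                                                families_per_replicate = 100,
                                                seed = 4),
                 rules = exclusion_rules(min_cases = 50),
                 min_cases_household = 225)
res$summary
```

The summary has one row per disease: case counts, the bootstrap-mean h²
and c² (in percent) with their percentile intervals, the boundary-LRT
p-values with their FDR-adjusted versions, whether the household term was
included, and the shape label of the bootstrap distribution.
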