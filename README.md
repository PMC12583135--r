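# pedherit

Variance-components heritability from extended family histories.

Family-history registries collect, from each participating proband, the
structure of their extended family (parents, siblings, grandparents,
half-siblings, ...) and which relatives had which diseases at what age.
`pedherit` estimates, from many such pedigrees, how much of the variance of
a binary disease trait is attributable to additive genetics (heritability,
h²), to an environment shared by the whole family (household effect, c²),
and to individual-specific factors (e²).  It is aimed at epidemiologists
and statistical geneticists working with proband-reported pedigree data,
and at methodologists who want a fully simulatable testbed for this class
of model.

## The model

The phenotype vector of each family is modelled as multivariate normal
with covariance

    Omega = 2 * Phi * sigma_g^2  +  H * sigma_c^2  +  I * sigma_e^2

where `Phi` is the kinship matrix from the classical pedigree recursion
(parent-child and full siblings share 50% of their genetic factors,
grandparent-grandchild and half-siblings 25%, unrelated partners 0%) and
`H` is an all-ones household matrix (each family shares one household).
Fixed effects (sex, age, age², and their interactions, with the per-disease
age precedence onset > assessment > death) and the total variance are
profiled out in closed form, so maximum likelihood runs over the variance
proportions (h², c²) on the unit simplex.  Component significance uses
boundary-corrected likelihood-ratio tests (½χ²₀ + ½χ²₁); sampling
variability uses a family-level bootstrap (whole families resampled with
replacement) with percentile intervals and normality/bimodality
diagnostics of the bootstrap distribution, which reflect the underlying
genetic architecture (polygenic vs. sporadic/monogenic mixtures).
P-values are Benjamini-Hochberg adjusted across diseases.

A liability-threshold simulator (`simulate_cohort()`) generates extended
families with known (h², c², e²), gene-dropped additive values, calibrated
disease prevalences, onset ages linked to liability, and optional fully
dominant monogenic families - so the whole pipeline validates against
known truth without any external data.

## Worked example

```r
library(pedherit)

cfg <- sim_config(n_families = 400, seed = 90)   # AD-like + two stroke-like diseases
co  <- simulate_cohort(cfg)
co
#> Pedigree cohort: 4790 individuals in 400 families
#> Diseases (cases): AD=384, iCVA=115, hCVA=101

bt <- run_bootstrap(co, "AD",
                    bootstrap_config(n_replicates = 200,
                                     families_per_replicate = 100,
                                     seed = 4, include_household = FALSE),
                    trait = "status")
bt
#> Family bootstrap for 'AD' (status scale): 200 successful / 0 failed replicates
#>   h2 = 0.321 (95% CI 0.170-0.463)
#>   bootstrap distribution: unimodal-normal (normality p = 0.511, bimodality coefficient = 0.355)

d   <- build_design(co, "AD")
st  <- cohortStructures(co, ids = d$ids)
fit <- fit_polygenic(d, st, include_household = FALSE)
fit
#> Polygenic variance-components fit: 'AD' (status scale)
#>   h2 = 0.325  e2 = 0.675  (total variance 0.07268)
#>   p(h2 > 0) = 9.409e-55
#>   4790 individuals, 400 families; converged = TRUE
```

The bootstrap mean h² of 0.32 (95% percentile interval 0.17-0.46) is the
observed-scale heritability of the simulated 8%-prevalence disease: about
a third of the 0/1-scale variance is attributable to additive genetics in
this cohort, the boundary LRT rejects h² = 0 decisively, and the
approximately normal bootstrap distribution is the signature of a purely
polygenic architecture (a rare disease with fully penetrant dominant
families instead produces skewed or bimodal estimates - see the vignette).
Note the observed 0/1 scale attenuates liability-scale variance
proportions; `liability_scale_transform()` provides the classical
conversion.

The multi-disease driver `run_study()` chains the exclusion filters
(rare-disease and early-onset rules), automatic household inclusion for
diseases with at least 225 cases, per-disease bootstraps, and FDR
adjustment, and writes a publication-style summary table plus replicate
and exclusion logs.

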