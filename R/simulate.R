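## Family-history simulator: extended pedigrees with known variance
## structure and liability-threshold binary diseases, for validating the
## kinship / variance-components / bootstrap machinery without real data.

#' Simulation configuration
#'
#' Parameters of the synthetic family-history generator.  Defaults emulate a
#' volunteer brain-research registry: three-generation families reported by a
#' participant in the youngest adult generation, an Alzheimer-like disease at
#' 8% cohort prevalence with onset around 77 +/- 9 years, and stroke-like
#' diseases at ~2% prevalence with onset around 69 years.
#'
#' @param n_families number of families to generate (>= 0).
#' @param generations generations per family, 2--4.
#' @param mean_children_per_couple Poisson mean number of children per
#'   partnership (the founding couple is guaranteed at least one child so
#'   every family spans two generations).
#' @param mate_probability probability that a non-final-generation child
#'   acquires a partner (and may reproduce).
#' @param repartner_probability probability that a partnered child takes a
#'   second partner, producing half-sibships.
#' @param target_prevalences named numeric vector, disease -> cohort
#'   prevalence in (0, 1).
#' @param true_h2,true_c2 simulated variance proportions of the liability
#'   attributable to additive genetics and to the family household;
#'   `true_h2 + true_c2 <= 1`.
#' @param onset_mean,onset_sd named numeric vectors (per disease): location
#'   and noise scale, in years, of the age-at-onset model.
#' @param onset_slope years of onset advance per unit of liability in excess
#'   of the disease threshold (larger liability -> earlier onset).
#' @param sex_effect,age_effect fixed-effect sizes on the liability scale
#'   for sex (centered +/- 0.5 coding) and standardised attained age.
#' @param monogenic_family_fraction fraction of families carrying a fully
#'   dominant monogenic risk allele (see [inject_monogenic_families()]).
#' @param monogenic_penetrance penetrance of the monogenic allele.
#' @param monogenic_disease disease the monogenic allele acts on (default:
#'   first entry of `target_prevalences`).
#' @param assessment_year calendar year of assessment.
#' @param generation_gap mean parent-child age difference, years.
#' @param proband_age mean age of the youngest generation at assessment.
#' @param lifespan_mean,lifespan_sd normal lifespan model (years) used to
#'   decide vital status; with the default age structure roughly half of a
#'   three-generation cohort is deceased.
#' @param seed integer seed; all `simulate_*` functions are deterministic
#'   given the config.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 1000L,
                       generations = 3L,
                       mean_children_per_couple = 2.5,
                       mate_probability = 0.75,
                       repartner_probability = 0.08,
                       target_prevalences = c(AD = 0.08, iCVA = 0.024,
                                              hCVA = 0.021),
                       true_h2 = 0.6,
                       true_c2 = 0.1,
                       onset_mean = c(AD = 77, iCVA = 69, hCVA = 69),
                       onset_sd = c(AD = 8.8, iCVA = 14, hCVA = 15),
                       onset_slope = 5,
                       sex_effect = 0.2,
                       age_effect = 0.3,
                       monogenic_family_fraction = 0,
                       monogenic_penetrance = 0.9,
                       monogenic_disease = NULL,
                       assessment_year = 2024L,
                       generation_gap = 28,
                       proband_age = 62,
                       lifespan_mean = 78,
                       lifespan_sd = 12,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              generations = as.integer(generations),
              mean_children_per_couple = mean_children_per_couple,
              mate_probability = mate_probability,
              repartner_probability = repartner_probability,
              target_prevalences = target_prevalences,
              true_h2 = true_h2, true_c2 = true_c2,
              onset_mean = onset_mean, onset_sd = onset_sd,
              onset_slope = onset_slope,
              sex_effect = sex_effect, age_effect = age_effect,
              monogenic_family_fraction = monogenic_family_fraction,
              monogenic_penetrance = monogenic_penetrance,
              monogenic_disease = monogenic_disease %||%
                names(target_prevalences)[1],
              assessment_year = as.integer(assessment_year),
              generation_gap = generation_gap,
              proband_age = proband_age,
              lifespan_mean = lifespan_mean, lifespan_sd = lifespan_sd,
              seed = as.integer(seed))
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_families >= 0L,
              generations >= 2L, generations <= 4L,
              mean_children_per_couple > 0)
    probs <- c(mate_probability, repartner_probability,
               monogenic_family_fraction, monogenic_penetrance,
               true_h2, true_c2, target_prevalences)
    if (any(probs < 0 | probs > 1)) {
      stop("probabilities and variance proportions must lie in [0, 1]")
    }
    if (true_h2 + true_c2 > 1) {
      stop("true_h2 + true_c2 must not exceed 1 (got ",
           true_h2 + true_c2, ")")
    }
    if (any(target_prevalences <= 0 | target_prevalences >= 1)) {
      stop("target prevalences must lie strictly in (0, 1)")
    }
    if (is.null(names(target_prevalences)) ||
        any(!nzchar(names(target_prevalences)))) {
      stop("target_prevalences must be a named vector")
    }
  })
  invisible(cfg)
}

## stage-specific seeds derived from the config seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) + c(structure = 0L, liability = 104729L,
                             monogenic = 224737L)[[stage]]) %%
    .Machine$integer.max
}

#' Simulate a set of extended families
#'
#' Generates `n_families` pedigrees of 2--4 generations.  Each family starts
#' from one founding couple; children partner with probability
#' `mate_probability` (partners are unrelated founders married into the
#' family), may re-partner with probability `repartner_probability` (creating
#' half-sibships), and reproduce with a Poisson number of children.  Birth
#' years follow the configured generation spacing; vital status comes from a
#' normal lifespan model, so the oldest generations are mostly deceased and
#' the youngest alive, mimicking proband-reported family histories.
#' Phenotypes are not assigned here; see [simulate_liability_and_disease()].
#'
#' @param config a [sim_config()].
#' @return a `ped_cohort` with empty disease set.
#' @export
simulate_pedigree_set <- function(config) {
  .validate_sim_config(config)
  set.seed(.stage_seed(config$seed, "structure"))
  fams <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    fams[[i]] <- .simulate_one_family(sprintf("F%05d", i), config)
  }
  ind <- if (length(fams)) {
    do.call(rbind, fams)
  } else {
    .empty_individuals()
  }
  ind <- .assign_vital_status(ind, config)
  cohort(ind, diseases = character())
}

.empty_individuals <- function() {
  data.frame(fid = character(), iid = character(), pat = character(),
             mat = character(), sex = integer(), generation = integer(),
             birth_year = numeric(), alive = logical(),
             age_at_assessment = numeric(), age_at_death = numeric(),
             stringsAsFactors = FALSE)
}

## One family: loops generations; within a generation all draws vectorised.
.simulate_one_family <- function(fid, config) {
  G <- config$generations
  counter <- 0L
  nid <- function(k) {
    ids <- sprintf("%s_%03d", fid, counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  byear <- function(gen, k) {
    mu <- config$assessment_year - config$proband_age -
      config$generation_gap * (G - gen)
    round(rnorm(k, mu, 4))
  }
  rows <- list()
  add <- function(iid, pat, mat, sex, gen, by) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fid = fid, iid = iid, pat = pat, mat = mat, sex = sex,
      generation = gen, birth_year = by, stringsAsFactors = FALSE)
  }
  f0 <- nid(1); m0 <- nid(1)
  add(f0, "0", "0", 1L, 1L, byear(1L, 1))
  add(m0, "0", "0", 2L, 1L, byear(1L, 1))
  ## couples reproducing into generation g+1: father id, mother id, founding?
  couples <- data.frame(pat = f0, mat = m0, founding = TRUE,
                        stringsAsFactors = FALSE)
  for (g in seq_len(G - 1L)) {
    if (!nrow(couples)) break
    nextc <- list()
    nkid <- rpois(nrow(couples), config$mean_children_per_couple)
    nkid[couples$founding] <- pmax(1L, nkid[couples$founding])
    for (ci in seq_len(nrow(couples))) {
      k <- nkid[ci]
      if (k == 0L) next
      kid <- nid(k)
      sex <- 1L + rbinom(k, 1L, 0.5)
      add(kid, couples$pat[ci], couples$mat[ci], sex, g + 1L, byear(g + 1L, k))
      if (g + 1L < G) {
        mated <- runif(k) < config$mate_probability
        for (j in which(mated)) {
          npart <- 1L + rbinom(1L, 1L, config$repartner_probability)
          for (p in seq_len(npart)) {
            sp <- nid(1)
            add(sp, "0", "0", 3L - sex[j], g + 1L, byear(g + 1L, 1))
            nextc[[length(nextc) + 1L]] <- data.frame(
              pat = if (sex[j] == 1L) kid[j] else sp,
              mat = if (sex[j] == 1L) sp else kid[j],
              founding = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
    couples <- if (length(nextc)) do.call(rbind, nextc) else couples[0, ]
  }
  do.call(rbind, rows)
}

.assign_vital_status <- function(ind, config) {
  n <- nrow(ind)
  lifespan <- pmax(25, rnorm(n, config$lifespan_mean, config$lifespan_sd))
  attained <- config$assessment_year - ind$birth_year
  ind$alive <- lifespan > attained
  ind$age_at_assessment <- ifelse(ind$alive, attained, NA_real_)
  ind$age_at_death <- ifelse(ind$alive, NA_real_, round(lifespan, 1))
  ind
}

## attained age: current age if alive, age at death otherwise
.attained_age <- function(ind, config = NULL) {
  ifelse(ind$alive, ind$age_at_assessment, ind$age_at_death)
}

#' Simulate liabilities and binary disease status
#'
#' For each configured disease, assigns every individual a latent liability
#' \eqn{l = x_{fixed} + a + c + e}: a fixed-effect part (sex and standardised
#' attained age), an additive genetic value obtained by gene dropping
#' (founders drawn with variance `true_h2`; offspring = mid-parent +
#' Mendelian-sampling deviate of variance `true_h2 / 2`), a household effect
#' drawn once per family with variance `true_c2`, and an individual residual
#' with variance `1 - true_h2 - true_c2`.  Disease status is 1 when the
#' liability exceeds the threshold calibrated so that the realised cohort
#' prevalence matches `target_prevalences` (the empirical quantile of the
#' simulated liabilities).  Affected individuals receive an age at onset
#' `onset_mean - onset_slope * (l - threshold) + N(0, onset_sd)`, truncated
#' to `[1, attained age]`, so higher liability means earlier onset.
#' Liabilities are retained in `<disease>_liability` columns for validation.
#'
#' @param cohort a `ped_cohort` from [simulate_pedigree_set()].
#' @param config the same [sim_config()].
#' @return the cohort with status/onset/liability columns per disease.
#' @export
simulate_liability_and_disease <- function(cohort, config) {
  .validate_sim_config(config)
  stopifnot(inherits(cohort, "ped_cohort"))
  ind <- cohort$individuals
  if (!nrow(ind)) {
    cohort$diseases <- names(config$target_prevalences)
    for (d in cohort$diseases) {
      ind[[paste0(d, "_status")]] <- integer()
      ind[[paste0(d, "_onset")]] <- numeric()
      ind[[paste0(d, "_liability")]] <- numeric()
    }
    cohort$individuals <- ind
    return(cohort)
  }
  set.seed(.stage_seed(config$seed, "liability"))
  sg2 <- config$true_h2
  sc2 <- config$true_c2
  se2 <- 1 - sg2 - sc2
  age <- .attained_age(ind)
  age_z <- (age - mean(age)) / max(sd(age), 1e-8)
  xfix <- config$sex_effect * (ind$sex - 1.5) + config$age_effect * age_z
  for (d in names(config$target_prevalences)) {
    K <- config$target_prevalences[[d]]
    a <- .gene_drop(ind, sg2)
    cfam <- rnorm(length(unique(ind$fid)), 0, sqrt(sc2))
    names(cfam) <- unique(ind$fid)
    e <- rnorm(nrow(ind), 0, sqrt(se2))
    liab <- xfix + a + cfam[ind$fid] + e
    thr <- unname(quantile(liab, 1 - K, type = 7))
    aff <- liab > thr
    om <- config$onset_mean[[d]] %||% 70
    osd <- config$onset_sd[[d]] %||% 10
    onset <- om - config$onset_slope * (liab - thr) + rnorm(nrow(ind), 0, osd)
    onset <- pmin(pmax(round(onset, 1), 1), age)
    ind[[paste0(d, "_status")]] <- as.integer(aff)
    ind[[paste0(d, "_onset")]] <- ifelse(aff, onset, NA_real_)
    ind[[paste0(d, "_liability")]] <- unname(liab)
  }
  cohort$individuals <- ind
  cohort$diseases <- names(config$target_prevalences)
  cohort
}

## additive genetic values by gene dropping, vectorised per pedigree depth
.gene_drop <- function(ind, sg2) {
  n <- nrow(ind)
  a <- rep(NA_real_, n)
  fi <- match(ind$pat, ind$iid)   # NA for founders / married-in
  mi <- match(ind$mat, ind$iid)
  founder <- is.na(fi) & is.na(mi)
  a[founder] <- rnorm(sum(founder), 0, sqrt(sg2))
  repeat {
    ready <- is.na(a) & !is.na(fi) & !is.na(mi) & !is.na(a[fi]) & !is.na(a[mi])
    if (!any(ready)) break
    a[ready] <- 0.5 * (a[fi[ready]] + a[mi[ready]]) +
      rnorm(sum(ready), 0, sqrt(sg2 / 2))
  }
  if (anyNA(a)) {
    ## single known parent: unknown parent acts as an unobserved founder
    left <- which(is.na(a))
    for (i in left) {
      pa <- if (!is.na(fi[i])) a[fi[i]] else rnorm(1, 0, sqrt(sg2))
      ma <- if (!is.na(mi[i])) a[mi[i]] else rnorm(1, 0, sqrt(sg2))
      a[i] <- 0.5 * (pa + ma) + rnorm(1, 0, sqrt(sg2 / 2))
    }
  }
  a
}

#' Inject autosomal-dominant monogenic families
#'
#' In a configured fraction of families, a fully dominant risk allele for
#' `monogenic_disease` is dropped from one founder: each child of a carrier
#' inherits the allele with probability 1/2.  Carriers become affected with
#' probability `monogenic_penetrance`, overriding their polygenic status
#' (non-penetrant carriers keep the polygenic status).  Newly affected
#' carriers receive an onset drawn from the disease onset model.  Carrier
#' state is recorded in the `monogenic_carrier` column.  Used to emulate the
#' mixture of sporadic and autosomal-dominant families that makes bootstrap
#' heritability distributions depart from normality.
#'
#' @param cohort a phenotyped `ped_cohort`.
#' @param config the [sim_config()] (fields `monogenic_*`).
#' @return the modified cohort.
#' @export
inject_monogenic_families <- function(cohort, config) {
  .validate_sim_config(config)
  stopifnot(inherits(cohort, "ped_cohort"))
  frac <- config$monogenic_family_fraction
  if (frac == 0 || !nrow(cohort$individuals)) return(cohort)
  set.seed(.stage_seed(config$seed, "monogenic"))
  ind <- cohort$individuals
  d <- config$monogenic_disease
  sc <- paste0(d, "_status")
  if (!sc %in% names(ind)) stop("monogenic disease '", d, "' not simulated")
  fids <- unique(ind$fid)
  n_mono <- round(frac * length(fids))
  mono_fids <- sample(fids, n_mono)
  carrier <- rep(FALSE, nrow(ind))
  fi <- match(ind$pat, ind$iid)
  mi <- match(ind$mat, ind$iid)
  for (fm in mono_fids) {
    rows <- which(ind$fid == fm)
    founders <- rows[is.na(fi[rows]) & is.na(mi[rows])]
    carrier[founders[1]] <- TRUE
  }
  ## transmit down the pedigree: each child tested once, in depth order, with
  ## probability 1 - (1/2)^(number of carrier parents)
  ord <- order(.pedigree_depth(fi, mi))
  for (i in ord) {
    if (carrier[i]) next
    ncp <- sum(c(!is.na(fi[i]) && carrier[fi[i]],
                 !is.na(mi[i]) && carrier[mi[i]]))
    if (ncp > 0 && runif(1) < 1 - 0.5^ncp) carrier[i] <- TRUE
  }
  penetrant <- carrier & runif(nrow(ind)) < config$monogenic_penetrance
  newly <- penetrant & (is.na(ind[[sc]]) | ind[[sc]] != 1L)
  ind[[sc]][penetrant] <- 1L
  oc <- paste0(d, "_onset")
  if (any(newly)) {
    om <- config$onset_mean[[d]] %||% 70
    osd <- config$onset_sd[[d]] %||% 10
    onset <- round(rnorm(sum(newly), om, osd), 1)
    age <- .attained_age(ind)[newly]
    ind[[oc]][newly] <- pmin(pmax(onset, 1), age)
  }
  ind$monogenic_carrier <- carrier
  cohort$individuals <- ind
  cohort
}

#' Simulate a complete phenotyped cohort
#'
#' Convenience wrapper: pedigree structure, liabilities and disease status,
#' and (when `monogenic_family_fraction > 0`) monogenic families, in one
#' call.
#'
#' @param config a [sim_config()].
#' @return a phenotyped `ped_cohort`.
#' @export
simulate_cohort <- function(config) {
  x <- simulate_pedigree_set(config)
  x <- simulate_liability_and_disease(x, config)
  inject_monogenic_families(x, config)
}

## generation depth from parent indices; returns Inf on parent cycles
.pedigree_depth <- function(fi, mi) {
  n <- length(fi)
  depth <- ifelse(is.na(fi) & is.na(mi), 0L, NA_integer_)
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (i in todo) {
      dp <- c(if (!is.na(fi[i])) depth[fi[i]] else 0L,
              if (!is.na(mi[i])) depth[mi[i]] else 0L)
      if (!anyNA(dp)) depth[i] <- max(dp) + 1L
    }
  }
  depth[is.na(depth)] <- Inf
  depth
}
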