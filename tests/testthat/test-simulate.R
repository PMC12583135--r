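# Family-history simulator: structure, liability model, monogenic
# injection, file round trips.

test_that("empty and deterministic cases behave", {
  cfg <- sim_config(n_families = 0, seed = 3)
  empty <- simulate_cohort(cfg)
  expect_s3_class(empty, "ped_cohort")
  expect_equal(nrow(empty$individuals), 0L)

  cfg2 <- sim_config(n_families = 25, seed = 17)
  a <- simulate_cohort(cfg2)
  b <- simulate_cohort(cfg2)
  expect_identical(a, b)
})

test_that("generated structure has sibships, half-sibships and grandparents", {
  cfg <- sim_config(n_families = 200, generations = 3,
                    repartner_probability = 0.3, seed = 5)
  co <- simulate_pedigree_set(cfg)
  ind <- co$individuals
  expect_equal(length(unique(ind$fid)), 200L)
  expect_equal(nrow(validate_pedigree(co)), 0L)
  # every family spans at least two generations
  gens <- tapply(ind$generation, ind$fid, function(g) length(unique(g)))
  expect_true(all(gens >= 2))
  # full sibships exist
  expect_gt(nrow(sib_pairs(co)), 0)
  # half-sibs: same father, different mothers (via re-partnering)
  kid <- ind[ind$pat != "0", ]
  halfsib <- any(tapply(kid$mat, kid$pat, function(m) length(unique(m))) > 1)
  expect_true(halfsib)
  # three-generation chains imply grandparents
  par_of <- function(i) ind$pat[match(i, ind$iid)]
  gp <- par_of(par_of(ind$iid))
  expect_true(any(!is.na(gp) & gp != "0"))
})

test_that("mean family size matches the large-sample Monte-Carlo oracle", {
  # frozen oracle: a 50,000-family run of this generator at generations = 3,
  # mean_children_per_couple = 2.5 gave mean size 11.885440 (SD 6.747493)
  oracle_mean <- 11.885440
  oracle_sd <- 6.747493
  cfg <- sim_config(n_families = 2000, generations = 3,
                    mean_children_per_couple = 2.5, seed = 21)
  co <- simulate_pedigree_set(cfg)
  sizes <- as.vector(table(co$individuals$fid))
  se <- sqrt(oracle_sd^2 / 50000 + var(sizes) / length(sizes))
  expect_lt(abs(mean(sizes) - oracle_mean), 3 * se)
})

test_that("sibling liability correlation matches the additive model", {
  # with no fixed effects, cov(sibs) = h2/2 + c2 on the liability scale
  base <- list(n_families = 2000, sex_effect = 0, age_effect = 0)
  co0 <- simulate_cohort(do.call(sim_config, c(base, list(
    true_h2 = 0, true_c2 = 0, seed = 11))))
  sp <- sib_pairs(co0)
  expect_gt(nrow(sp), 5000)
  l <- co0$individuals$AD_liability
  r0 <- cor(l[sp[, 1]], l[sp[, 2]])
  expect_lt(abs(r0), 3 / sqrt(nrow(sp)))

  co1 <- simulate_cohort(do.call(sim_config, c(base, list(
    true_h2 = 0.6, true_c2 = 0.1, seed = 12))))
  sp1 <- sib_pairs(co1)
  l1 <- co1$individuals$AD_liability
  r1 <- cor(l1[sp1[, 1]], l1[sp1[, 2]])
  expect_lt(abs(r1 - 0.40), 3 / sqrt(nrow(sp1)))
})

test_that("parent-offspring and cross-family liability covariances", {
  cfg <- sim_config(n_families = 2000, sex_effect = 0, age_effect = 0,
                    true_h2 = 0.5, true_c2 = 0.2, seed = 31)
  co <- simulate_cohort(cfg)
  l <- co$individuals$AD_liability
  pp <- po_pairs(co)
  expect_gt(nrow(pp), 5000)
  # cov(parent, offspring) = sg2/2 + sc2 = 0.45
  cv <- cov(l[pp[, 1]], l[pp[, 2]])
  expect_lt(abs(cv - 0.45), 3 * sd(l[pp[, 1]] * l[pp[, 2]]) / sqrt(nrow(pp)))
  # individuals in different families are uncorrelated
  set.seed(1)
  i <- sample(nrow(co$individuals), 6000, replace = TRUE)
  j <- sample(nrow(co$individuals), 6000, replace = TRUE)
  keep <- co$individuals$fid[i] != co$individuals$fid[j]
  r <- cor(l[i[keep]], l[j[keep]])
  expect_lt(abs(r), 3 / sqrt(sum(keep)))
})

test_that("gene dropping preserves additive variance across generations", {
  cfg <- sim_config(n_families = 1200, sex_effect = 0, age_effect = 0,
                    true_h2 = 0.6, true_c2 = 0, seed = 41)
  co <- simulate_cohort(cfg)
  ind <- co$individuals
  expect_gt(nrow(ind), 10000)
  # with c2 = 0 and no fixed effects the liability is a + e, so each
  # generation's liability variance is sg2 + se2 = 1
  for (g in sort(unique(ind$generation))) {
    v <- var(ind$AD_liability[ind$generation == g])
    n <- sum(ind$generation == g)
    expect_lt(abs(v - 1), 3 * sqrt(2 / (n - 1)))
  }
})

test_that("realised prevalence matches the target", {
  co <- simulate_cohort(sim_config(n_families = 1000, seed = 51))
  st <- co$individuals$AD_status
  k <- mean(st)
  expect_lt(abs(k - 0.08), 3 * sqrt(0.08 * 0.92 / length(st)))
  # onset decreases with liability among the affected (on the subset where
  # the onset was not truncated to the individual's attained age)
  aff <- which(st == 1L)
  onset <- co$individuals$AD_onset[aff]
  attained <- with(co$individuals[aff, ],
                   ifelse(alive, age_at_assessment, age_at_death))
  free <- onset > 1 & onset < attained
  r <- cor(co$individuals$AD_liability[aff][free], onset[free])
  expect_lt(r, -3 / sqrt(sum(free)))   # clearly negative link
  expect_true(all(is.na(co$individuals$AD_onset[st == 0L])))
})

test_that("monogenic injection follows Mendelian transmission", {
  cfg <- sim_config(n_families = 400, seed = 61,
                    monogenic_family_fraction = 0)
  co <- simulate_cohort(cfg)
  expect_identical(inject_monogenic_families(co, cfg), co)

  cfg1 <- sim_config(n_families = 400, seed = 61,
                     monogenic_family_fraction = 1,
                     monogenic_penetrance = 1)
  co1 <- inject_monogenic_families(co, cfg1)
  ind <- co1$individuals
  # every family carries at least one affected founder carrier
  aff_by_fam <- tapply(ind$AD_status, ind$fid, function(s) any(s == 1L))
  expect_true(all(aff_by_fam))
  # among children of carriers, carrier fraction ~ 1/2
  fi <- match(ind$pat, ind$iid); mi <- match(ind$mat, ind$iid)
  one_carrier <- !is.na(fi) & !is.na(mi) &
    xor(ind$monogenic_carrier[fi], ind$monogenic_carrier[mi])
  frac <- mean(ind$monogenic_carrier[one_carrier])
  n <- sum(one_carrier)
  expect_gt(n, 200)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  # penetrance 1: every carrier is affected
  expect_true(all(ind$AD_status[ind$monogenic_carrier] == 1L))
})

test_that("cohort files round-trip and a config round-trips", {
  co <- simulate_cohort(sim_config(n_families = 12, seed = 71))
  ped <- withr::local_tempfile(fileext = ".ped")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, ped, phe)
  back <- read_cohort(ped, phe)
  expect_equal(back$individuals, co$individuals)
  expect_setequal(back$diseases, co$diseases)

  # identical config + seed => bit-identical files
  ped2 <- withr::local_tempfile(fileext = ".ped")
  phe2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(simulate_cohort(sim_config(n_families = 12, seed = 71)),
               ped2, phe2)
  expect_identical(readLines(ped), readLines(ped2))
  expect_identical(readLines(phe), readLines(phe2))

  cfgf <- withr::local_tempfile(fileext = ".yaml")
  cfg <- sim_config(n_families = 12, seed = 71)
  write_sim_config(cfg, cfgf)
  expect_equal(read_sim_config(cfgf), cfg)
})

test_that("malformed pedigree files are reported with line numbers", {
  co <- cohort(with_disease(nuclear_family(), "ad", affected = "dad",
                            onset = c(dad = 70)))
  ped <- withr::local_tempfile(fileext = ".ped")
  phe <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, ped, phe)

  lines <- readLines(ped)
  bad <- sub("dad mum", "ghost mum", lines[4], fixed = TRUE)
  f1 <- withr::local_tempfile(); writeLines(c(lines[1:3], bad, lines[5]), f1)
  expect_error(read_cohort(f1, phe), "ghost")

  bad2 <- sub(" 1$", " 3", lines[2])
  f2 <- withr::local_tempfile(); writeLines(c(lines[1], bad2, lines[3:5]), f2)
  expect_error(read_cohort(f2, phe), "sex")

  f3 <- withr::local_tempfile()
  writeLines(c(lines, lines[2]), f3)
  expect_error(read_cohort(f3, phe), "duplicate")

  f4 <- withr::local_tempfile()
  writeLines(c(lines, "FAM1 extra"), f4)
  expect_error(read_cohort(f4, phe), "line 6")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(true_h2 = 0.7, true_c2 = 0.5), "exceed 1")
  expect_error(sim_config(target_prevalences = c(AD = 0)), "strictly")
  expect_error(sim_config(generations = 5))
  expect_error(sim_config(mate_probability = 1.2), "\\[0, 1\\]")
})
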