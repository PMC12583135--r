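# Covariance assembly, likelihood oracles, the ML fitter and the boundary
# likelihood-ratio machinery.

trio_structure <- function() {
  trio <- ped_df(iid = c("p1", "p2", "c1"), pat = c("0", "0", "p1"),
                 mat = c("0", "0", "p2"), sex = c(1L, 2L, 1L))
  relatedness_matrix(cohort(trio), "FAM1")
}

test_that("model covariance evaluates the printed equation", {
  s <- trio_structure()
  vc <- variance_components(sigma_g2 = 1, sigma_c2 = 0, sigma_e2 = 0.5)
  om <- model_covariance(s, vc, include_household = FALSE)
  expect_equal(unname(om[1, 3]), 0.5)   # parent-child: 2Phi = 0.5 times sg2
  expect_equal(unname(om[1, 2]), 0)     # founders unrelated
  expect_equal(unname(diag(om)), rep(1.5, 3))
  expect_identical(om, t(om))

  # pure noise: identity
  vc0 <- variance_components(0, 0, 1)
  expect_equal(unname(model_covariance(s, vc0, FALSE)), diag(3))

  # household adds a constant block
  vch <- variance_components(1, 0.3, 0.5)
  omh <- model_covariance(s, vch, include_household = TRUE)
  expect_equal(unname(omh[1, 2]), 0.3)
  expect_equal(unname(diag(omh)), rep(1.8, 3))
})

test_that("block likelihood equals closed forms and the dense oracle", {
  # single individual, y = 0, beta = 0, sigma_e2 = 1: standard normal density
  d1 <- manual_design(y = 0, X = matrix(1, 1, 1,
                                        dimnames = list(NULL, "intercept")),
                      fid = "FAM1", ids = "solo")
  s1 <- list(FAM1 = relatedness_matrix(cohort(ped_df("solo", "0", "0", 1L)),
                                       "FAM1"))
  vc <- variance_components(0, 0, 1)
  expect_equal(log_likelihood(d1, s1, vc, beta = 0,
                              include_household = FALSE),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # 3-member family vs dense multivariate-normal evaluation
  s <- trio_structure()
  y <- c(0.4, -0.3, 0.9)
  X <- cbind(intercept = 1, z = c(0.1, -0.2, 0.4))
  d3 <- manual_design(y, X, fid = rep("FAM1", 3),
                      ids = s$member_order)
  vc3 <- variance_components(0.7, 0.2, 0.4)
  beta <- c(0.05, -0.1)
  ll <- log_likelihood(d3, list(FAM1 = s), vc3, beta, TRUE)
  ll_dense <- dense_block_ll(d3, list(FAM1 = s), vc3, beta, TRUE)
  expect_equal(ll, ll_dense, tolerance = 1e-10)
})

test_that("family blocks add: split vs block-diagonal evaluation", {
  co <- simulate_cohort(sim_config(n_families = 6, seed = 2))
  d <- build_design(co, "AD", trait = "liability")
  st <- cohortStructures(co, ids = d$ids)
  vc <- variance_components(0.5, 0.1, 0.4)
  beta <- rep(0, ncol(d$covariates))
  ll_blocks <- log_likelihood(d, st, vc, beta, TRUE)
  ll_dense <- dense_block_ll(d, st, vc, beta, TRUE)
  expect_equal(ll_blocks, ll_dense, tolerance = 1e-10)

  # and the two halves sum to the whole
  half <- function(fids) {
    rows <- d$fid %in% fids
    dd <- manual_design(d$response[rows],
                        d$covariates[rows, , drop = FALSE],
                        d$fid[rows], d$ids[rows])
    log_likelihood(dd, st[fids], vc, beta, TRUE)
  }
  fids <- unique(d$fid)
  expect_equal(half(fids[1:3]) + half(fids[4:6]), ll_blocks,
               tolerance = 1e-10)
})

test_that("non-positive-definite covariance names the offending family", {
  s <- trio_structure()
  d3 <- manual_design(c(0, 0, 0), matrix(1, 3, 1), rep("FAM1", 3),
                      s$member_order)
  vc_bad <- structure(list(sigma_g2 = -2, sigma_c2 = 0, sigma_e2 = 0.1),
                      class = "variance_components")
  expect_error(log_likelihood(d3, list(FAM1 = s), vc_bad, 0, FALSE),
               "FAM1")
})

test_that("single-family fit matches an exhaustive grid-search oracle", {
  s <- trio_structure()
  y <- c(1.1, -0.4, 0.8)
  X <- matrix(1, 3, 1, dimnames = list(NULL, "intercept"))
  d <- manual_design(y, X, rep("FAM1", 3), s$member_order)
  fit <- fit_polygenic(d, list(FAM1 = s), include_household = FALSE,
                       compute_lrt = FALSE)

  # oracle: dense grid over (sg2, se2), intercept profiled by GLS,
  # evaluated in the eigenbasis of 2*Phi (independent of the fitter)
  eg <- eigen(s$relatedness, symmetric = TRUE)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, 3)))
  grid <- expand.grid(sg2 = seq(0, 1.5, by = 1e-3),
                      se2 = seq(1e-3, 1.5, by = 1e-3))
  ll <- numeric(nrow(grid))
  for (k in seq_len(3)) {
    dk <- grid$sg2 * eg$values[k] + grid$se2
    ll <- ll - 0.5 * log(dk)
  }
  num <- den <- qf <- 0
  dks <- lapply(1:3, function(k) grid$sg2 * eg$values[k] + grid$se2)
  num <- Reduce(`+`, lapply(1:3, function(k) xt[k] * yt[k] / dks[[k]]))
  den <- Reduce(`+`, lapply(1:3, function(k) xt[k]^2 / dks[[k]]))
  bhat <- num / den
  qf <- Reduce(`+`, lapply(1:3, function(k) {
    (yt[k] - xt[k] * bhat)^2 / dks[[k]]
  }))
  ll <- ll - 0.5 * qf - 1.5 * log(2 * pi)
  best <- which.max(ll)
  # the continuous optimiser may beat the discrete grid by up to the
  # likelihood variation across one grid cell
  expect_gte(fit$loglik_full, ll[best] - 1e-8)
  expect_lt(fit$loglik_full - ll[best], 2e-3)
  expect_equal(fit$components$sigma_g2, grid$sg2[best], tolerance = 5e-3)
  expect_equal(fit$components$sigma_e2, grid$se2[best], tolerance = 5e-3)
})

test_that("variance proportions are recovered on simulated families", {
  h2s <- c2s <- numeric(4)
  for (s in 1:4) {
    cfg <- sim_config(n_families = 250, seed = 300 + s)
    co <- simulate_cohort(cfg)
    d <- build_design(co, "AD", trait = "liability")
    st <- cohortStructures(co, ids = d$ids)
    fit <- fit_polygenic(d, st, include_household = TRUE,
                         min_cases_household = 0, compute_lrt = FALSE)
    h2s[s] <- fit$h2; c2s[s] <- fit$c2
    expect_true(fit$converged)
    expect_equal(fit$h2 + fit$c2 + fit$e2, 1, tolerance = 1e-8)
  }
  expect_lt(abs(mean(h2s) - 0.6), 0.1)
  expect_lt(abs(mean(c2s) - 0.1), 0.07)
})

test_that("adding a free component never lowers the likelihood", {
  co <- simulate_cohort(sim_config(n_families = 120, seed = 77))
  d <- build_design(co, "AD", trait = "liability")
  st <- cohortStructures(co, ids = d$ids)
  with_h <- fit_polygenic(d, st, include_household = TRUE,
                          min_cases_household = 0)
  no_h <- fit_polygenic(d, st, include_household = FALSE)
  expect_gte(with_h$loglik_full, no_h$loglik_full - 1e-6)
  expect_gte(with_h$loglik_full, with_h$loglik_no_g - 1e-6)
  expect_gte(with_h$loglik_full, with_h$loglik_no_c - 1e-6)
  expect_gte(no_h$loglik_full, no_h$loglik_no_g - 1e-6)
})

test_that("estimates are invariant to family and member ordering", {
  co <- simulate_cohort(sim_config(n_families = 40, seed = 55))
  d <- build_design(co, "AD", trait = "liability")
  st <- cohortStructures(co, ids = d$ids)
  ref <- fit_polygenic(d, st, include_household = TRUE,
                       min_cases_household = 0, compute_lrt = FALSE)

  set.seed(99)
  perm <- sample(length(d$response))
  dp <- manual_design(d$response[perm], d$covariates[perm, , drop = FALSE],
                      d$fid[perm], d$ids[perm])
  fp <- fit_polygenic(dp, st, include_household = TRUE,
                      min_cases_household = 0, compute_lrt = FALSE)
  expect_equal(fp$h2, ref$h2, tolerance = 1e-6)
  expect_equal(fp$c2, ref$c2, tolerance = 1e-6)
  expect_equal(fp$loglik_full, ref$loglik_full, tolerance = 1e-8)
})

test_that("unrelated individuals give a flat, flagged likelihood", {
  n <- 60
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    ped_df(iid = sprintf("s%03d", i), pat = "0", mat = "0",
           sex = 1L + i %% 2L, fid = sprintf("f%03d", i))
  }))
  set.seed(4)
  df$age_at_assessment <- runif(n, 40, 90)
  d_aff <- sprintf("s%03d", 1:10)
  df <- with_disease(df, "d", d_aff, setNames(runif(10, 60, 80), d_aff))
  co <- cohort(df)
  d <- build_design(co, "d")
  st <- cohortStructures(co, ids = d$ids)
  expect_warning(fit <- fit_polygenic(d, st, include_household = FALSE),
                 "flat")
  expect_false(fit$identifiable)
})

test_that("boundary LRT p-values are calibrated under the null", {
  cfg0 <- sim_config(n_families = 60, true_h2 = 0, true_c2 = 0, seed = 600)
  co <- simulate_pedigree_set(cfg0)
  ps <- numeric(60)
  for (r in seq_along(ps)) {
    cfg <- cfg0
    cfg$seed <- 600L + r
    x <- simulate_liability_and_disease(co, cfg)
    d <- build_design(x, "AD", trait = "liability")
    st <- cohortStructures(x, ids = d$ids)
    ps[r] <- fit_polygenic(d, st, include_household = FALSE)$p_h2
  }
  # about half the fits sit on the boundary (p = 1), the rest follow chi2(1)
  expect_lt(abs(mean(ps == 1) - 0.5), 3 * sqrt(0.25 / length(ps)))
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("household component is refused below the case threshold", {
  co <- simulate_cohort(sim_config(n_families = 100, seed = 13))
  d <- build_design(co, "AD")
  st <- cohortStructures(co, ids = d$ids)
  expect_lt(d$n_cases, 225)
  expect_error(fit_polygenic(d, st, include_household = TRUE),
               class = "pedherit_household_refused")
  fit <- fit_polygenic(d, st, include_household = FALSE,
                       compute_lrt = FALSE)
  expect_true(fit$converged)
})

test_that("liability-scale transform has the classical closed form", {
  expect_equal(liability_scale_transform(0, 0.1), 0)
  # K = 0.5: multiplier K(1-K)/phi(0)^2 = 0.25 / (1/(2*pi)) = pi/2
  expect_equal(liability_scale_transform(0.4, 0.5), 0.4 * pi / 2,
               tolerance = 1e-12)
  expect_lt(liability_scale_transform(0.3, 0.08),
            liability_scale_transform(0.6, 0.08))
  expect_error(liability_scale_transform(0.5, 1), "strictly")
})
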