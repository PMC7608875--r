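test_that("generation is bit-identical under the same config and seed", {
  cfg <- sim_config(n_countries = 2, clusters_per_country = 10,
                    children_per_cluster = 8, seed = 123)
  d1 <- generate_population(cfg)
  d2 <- generate_population(cfg)
  expect_identical(d1, d2)
  d3 <- generate_population(sim_config(n_countries = 2,
                                       clusters_per_country = 10,
                                       children_per_cluster = 8,
                                       seed = 124))
  expect_false(identical(d1, d3))
})

test_that("identical group models and covariate mixes give a null prevalence gap", {
  covs <- default_covariates()
  covs <- lapply(covs, function(cv) {
    cv$probs <- cv$probs_nonpoor
    cv$probs_poor <- cv$probs_nonpoor <- NULL
    cv
  })
  b <- c(-2.2, -0.25, -0.4, -0.2, -0.1, -0.6)
  cfg <- sim_config(n_countries = 1, clusters_per_country = 200,
                    children_per_cluster = 100, poor_fraction = 0.5,
                    covariates = covs, beta_poor = b, beta_nonpoor = b,
                    seed = 55)
  d <- generate_population(cfg)
  pp <- weighted_prevalence(d$severe_wasting[d$wealth == "poor"]) / 100
  pn <- weighted_prevalence(d$severe_wasting[d$wealth == "non-poor"]) / 100
  n_half <- nrow(d) / 2
  mc_se <- sqrt(2 * mean(d$severe_wasting) *
                  (1 - mean(d$severe_wasting)) / n_half)
  expect_lt(abs(pp - pn), 3 * mc_se)
  # the analytic ground truth is exactly null
  gt <- true_decomposition(cfg)
  expect_equal(gt$rd, 0)
  expect_equal(gt$threefold$population$gap, 0)
})

test_that("intercept-only models hit the logistic closed-form prevalences", {
  covs <- list(dummy = list(levels = c("a", "b"), probs = c(0.5, 0.5)))
  cfg <- sim_config(n_countries = 1, clusters_per_country = 400,
                    children_per_cluster = 500, poor_fraction = 0.5,
                    beta_poor = c(-3, 0), beta_nonpoor = c(-3.5, 0),
                    covariates = covs, seed = 77)
  d <- generate_population(cfg)
  # closed form: plogis(-3) = 4.7426%, plogis(-3.5) = 2.9312%
  for (g in c("poor", "non-poor")) {
    target <- if (g == "poor") plogis(-3) else plogis(-3.5)
    i <- d$wealth == g
    phat <- mean(d$severe_wasting[i])
    se <- sqrt(target * (1 - target) / sum(i))
    expect_lt(abs(phat - target), 3 * se)
  }
  gt <- true_decomposition(cfg)
  expect_equal(gt$prev_poor, 100 * plogis(-3))
  expect_equal(gt$prev_nonpoor, 100 * plogis(-3.5))
})

test_that("analytic ground truth obeys the decomposition limits", {
  cfg_eq_b <- sim_config(beta_poor = c(-2.5, -0.3, -0.4, -0.2, -0.1, -0.5),
                         beta_nonpoor = c(-2.5, -0.3, -0.4, -0.2, -0.1, -0.5))
  gt <- true_decomposition(cfg_eq_b)
  for (s in c("at_means", "population")) {
    expect_equal(gt$threefold[[s]]$C, 0)
    expect_equal(gt$threefold[[s]]$I, 0)
    expect_equal(gt$threefold[[s]]$gap, gt$threefold[[s]]$E)
    for (ref in c("A", "B"))
      expect_equal(unname(gt$twofold[[s]][[ref]]["U"]), 0)
  }

  covs <- lapply(default_covariates(), function(cv) {
    cv$probs <- cv$probs_poor
    cv$probs_poor <- cv$probs_nonpoor <- NULL
    cv
  })
  gt2 <- true_decomposition(sim_config(covariates = covs))
  for (s in c("at_means", "population")) {
    expect_equal(gt2$threefold[[s]]$E, 0)
    expect_equal(gt2$threefold[[s]]$I, 0)
    expect_equal(gt2$threefold[[s]]$gap, gt2$threefold[[s]]$C)
  }

  # additivity of truth in both schemes, all references
  gt3 <- true_decomposition(sim_config())
  for (s in c("at_means", "population")) {
    t3 <- gt3$threefold[[s]]
    expect_equal(t3$E + t3$C + t3$I, t3$gap, tolerance = 1e-12)
    for (ref in c("A", "B")) {
      t2 <- gt3$twofold[[s]][[ref]]
      expect_equal(unname(t2["Q"] + t2["U"]), t3$gap, tolerance = 1e-12)
    }
  }
})

test_that("global weight rescaling leaves downstream estimates unchanged", {
  cfg <- sim_config(n_countries = 1, clusters_per_country = 40,
                    children_per_cluster = 30, seed = 9)
  d <- generate_population(cfg)
  d2 <- transform(d, weight = weight * 13)
  covs <- names(default_covariates())
  r1 <- rd_inference(d); r2 <- rd_inference(d2)
  expect_equal(r1$rd, r2$rd)
  expect_equal(r1$se, r2$se)
  dec1 <- oaxaca_decompose(d, "severe_wasting", covs, weights = "weight")
  dec2 <- oaxaca_decompose(d2, "severe_wasting", covs, weights = "weight")
  expect_equal(dec1$E, dec2$E, tolerance = 1e-10)
  expect_equal(dec1$C, dec2$C, tolerance = 1e-10)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(poor_fraction = 1.3), "poor_fraction")
  expect_error(sim_config(n_countries = 0), "n_countries")
  expect_error(sim_config(beta_poor = c(-2, 1)), "beta_poor")
  covs <- default_covariates()
  covs$media_access$probs_poor <- c(0.6, 0.6)
  expect_error(sim_config(covariates = covs), "media_access")
  expect_error(sim_config(covariates = list()), "covariates")
  covs2 <- default_covariates()
  covs2$residence$probs_poor <- NULL
  expect_error(sim_config(covariates = covs2), "residence")
})

test_that("population tables and configs round-trip through CSV and YAML", {
  cfg <- sim_config(n_countries = 1, clusters_per_country = 6,
                    children_per_cluster = 5, seed = 3)
  d <- generate_population(cfg)
  f <- tempfile(fileext = ".csv")
  write_population(d, f)
  d2 <- read_population(f, cfg)
  for (v in names(default_covariates()))
    expect_equal(levels(d2[[v]]), levels(d[[v]]))
  expect_equal(d2$weight, d$weight, tolerance = 1e-12)
  expect_equal(d2$severe_wasting, d$severe_wasting)
  expect_equal(as.character(d2$wealth), as.character(d$wealth))

  fy <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, fy)
  cfg2 <- read_sim_config(fy)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  expect_identical(generate_population(cfg2), generate_population(cfg))
})

test_that("fits on generated data recover the generating coefficients", {
  cfg <- sim_config(n_countries = 1, clusters_per_country = 250,
                    children_per_cluster = 400, poor_fraction = 0.5,
                    seed = 101)
  d <- generate_population(cfg)
  covs <- names(default_covariates())
  m <- suppressWarnings(
    fit_group_model(d[d$wealth == "poor", ], "severe_wasting", covs,
                    weights = "weight", link = "logit", group = "poor",
                    normalization = "treatment"))
  se <- sqrt(diag(m$vcov))
  z <- abs(m$coef - cfg$beta_poor) / se
  expect_true(all(z < 3.5))
})
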