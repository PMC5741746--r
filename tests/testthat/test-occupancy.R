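# Occupancy likelihood, fitting and prediction.

test_that("occupancy likelihood has the right closed-form limits", {
  # one site, one visit, forced occupied (psi = 1), p = 0.5 -> -log(0.5)
  y <- matrix(1, 1, 1)
  nll <- occupancy_negloglik(c(qlogis(1 - 1e-12), 0), y)
  expect_equal(nll, -log(0.5), tolerance = 1e-6)
  # unoccupied certainty: all-zero history with psi -> 0 has likelihood 1
  y0 <- matrix(0, 1, 3)
  expect_equal(occupancy_negloglik(c(-40, 0), y0), 0, tolerance = 1e-10)
})

test_that("occupancy likelihood equals joint-state enumeration on small instances", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:4, 1); tmax <- sample(2:3, 1)
    y <- matrix(rbinom(n * tmax, 1, 0.4), n, tmax)
    if (rep == 3) y[1, tmax] <- NA   # ragged case
    L <- runif(n, 0.3, 5)
    par <- c(rnorm(1, 0, 0.7), rnorm(1, 0, 0.7))
    psi <- plogis(par[1] + log(L))
    p <- matrix(plogis(par[2]), n, tmax)
    expect_equal(
      occupancy_negloglik(par, y, offset_km = L),
      oracle_occu_nll(psi, p, y),
      tolerance = 1e-10)
  }
  # with a site-level detection covariate
  y <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)
  sc <- data.frame(x = c(-1, 0, 2))
  par <- c(0.3, -0.4, 0.5)
  psi <- rep(plogis(0.3), 3)
  p <- matrix(plogis(-0.4 + 0.5 * sc$x), 3, 2)
  expect_equal(occupancy_negloglik(par, y, site_covs = sc, det_covs = "x"),
               oracle_occu_nll(psi, p, y), tolerance = 1e-10)
})

test_that("parameter count and dimension checks behave", {
  d <- jersey_transects()
  y <- simulate_occupancy_history(d, seed = 5)
  sc <- scale_covariates(as.data.frame(d), "acos")
  f0 <- fit_occupancy(y, offset_km = d$transect_km, seed = 1)
  expect_identical(f0$npar, 2L)
  f1 <- fit_occupancy(y, site_covs = sc, det_covs = "acos",
                      offset_km = d$transect_km, seed = 1)
  expect_identical(f1$npar, 3L)
  # habitat enters as a 4-level factor: p(acos), psi(habitat) has 6 parameters
  f2 <- fit_occupancy(y, site_covs = sc, det_covs = "acos",
                      state_covs = "habitat", offset_km = d$transect_km, seed = 1)
  expect_identical(f2$npar, 6L)
  expect_error(occupancy_negloglik(c(0, 0, 0), y, offset_km = d$transect_km),
               class = "occumix_dimension_error")
})

test_that("perfect detection reduces the occupancy MLE to the naive proportion", {
  d <- generate_design(40, seed = 2)
  y <- simulate_occupancy_history(d, beta0 = qlogis(0.6), alpha0 = qlogis(0.999),
                                  offset = FALSE, seed = 3)
  f <- fit_occupancy(y, seed = 1)
  naive <- mean(apply(y, 1, function(r) any(r == 1, na.rm = TRUE)))
  expect_equal(plogis(f$coef[["state:(Intercept)"]]), naive, tolerance = 1e-3)
})

test_that("the per-km intercept is recovered at a large design", {
  d <- generate_design(400, seed = 7)
  y <- simulate_occupancy_history(d, beta0 = qlogis(0.44), alpha0 = qlogis(0.33),
                                  seed = 7)
  f <- fit_occupancy(y, offset_km = d$transect_km, seed = 1)
  expect_true(f$converged)
  # asymptotic SE from the fit bounds the Monte-Carlo tolerance
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$coef[["state:(Intercept)"]] - qlogis(0.44)), 4 * se[1])
  expect_lt(abs(f$coef[["det:(Intercept)"]] - qlogis(0.33)), 4 * se[2])
})

test_that("occupancy predictions follow the logit-plus-log-length offset", {
  # offset identity at unit length, and the two printed anchor transects
  expect_equal(occupancy_from_density(0.44, 1), 0.44)
  expect_equal(round(occupancy_from_density(0.44, 0.28), 2), 0.18)
  expect_equal(round(occupancy_from_density(0.44, 19.10), 2), 0.94)
  # strictly increasing in transect length
  lens <- seq(0.1, 20, length.out = 50)
  expect_true(all(diff(occupancy_from_density(0.44, lens)) > 0))
  expect_error(occupancy_from_density(0.44, -1), class = "occumix_domain_error")

  # the fit-based predictor agrees and carries an interval inside [0, 1]
  d <- jersey_transects()
  y <- simulate_occupancy_history(d, seed = 19)
  f <- fit_occupancy(y, offset_km = d$transect_km, seed = 1)
  pr <- predict_occupancy(f, c(0.28, 4.66, 19.1))
  psi_km <- plogis(f$coef[["state:(Intercept)"]])
  expect_equal(pr$estimate, occupancy_from_density(psi_km, c(0.28, 4.66, 19.1)))
  expect_true(all(pr$lower >= 0 & pr$lower <= pr$estimate &
                    pr$estimate <= pr$upper & pr$upper <= 1))
})

test_that("detection predictions invert the link and recover covariate signs", {
  expect_equal(predict_detection(qlogis(0.33))$estimate, 0.33)
  expect_equal(predict_detection(c(0, 0), newdata = data.frame(x = 3))$estimate, 0.5)
  # ACO-driven detection: fitted curve increases with effort
  d <- generate_design(150, seed = 21)
  y <- simulate_occupancy_history(d, alpha0 = study_detection_coefs()[1],
                                  alpha = c(acos = unname(study_detection_coefs()[2])),
                                  seed = 22)
  sc <- scale_covariates(as.data.frame(d), "acos")
  f <- fit_occupancy(y, site_covs = sc, det_covs = "acos",
                     offset_km = d$transect_km, seed = 1)
  curve <- predict_detection(f, newdata = data.frame(acos = c(0, 50, 100, 200)))
  expect_true(all(diff(curve$estimate) > 0))
  expect_error(predict_detection(f, newdata = data.frame(bogus = 1)),
               class = "occumix_schema_error")
})

test_that("maximised log-likelihood is invariant to covariate shift plus re-scaling", {
  d <- generate_design(30, seed = 30)
  y <- simulate_occupancy_history(d, seed = 31)
  raw <- as.data.frame(d)
  sc1 <- scale_covariates(raw, "acos")
  raw2 <- raw; raw2$acos <- raw2$acos + 137
  sc2 <- scale_covariates(raw2, "acos")
  f1 <- fit_occupancy(y, site_covs = sc1, det_covs = "acos",
                      offset_km = d$transect_km, seed = 1)
  f2 <- fit_occupancy(y, site_covs = sc2, det_covs = "acos",
                      offset_km = d$transect_km, seed = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("boundary data are warned about, not silently fitted", {
  y <- matrix(0, 5, 3)
  expect_warning(fit_occupancy(y, seed = 1), "boundary")
})
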