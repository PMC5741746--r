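# N-mixture likelihood, mixtures, empirical-Bayes abundance.

test_that("N-mixture likelihood has the right limits and matches the oracle", {
  # empty-population limit: y = 0, lambda -> 0 gives likelihood -> 1
  y0 <- matrix(0, 1, 1)
  expect_lt(nmixture_negloglik(c(-30, 0), y0, kmax = 10), 1e-10)

  # brute-force oracle on small instances, all three mixtures
  set.seed(4)
  y <- matrix(rpois(4, 1), 2, 2)
  lam_par <- 0; p_par <- 0   # lambda = 1, p = 0.5
  expect_equal(
    nmixture_negloglik(c(lam_par, p_par), y, kmax = 6),
    oracle_nmix_nll(rep(1, 2), matrix(0.5, 2, 2), y, 6),
    tolerance = 1e-10)
  yr <- y; yr[2, 2] <- NA
  expect_equal(
    nmixture_negloglik(c(0.3, -0.2), yr, kmax = 15),
    oracle_nmix_nll(rep(exp(0.3), 2), matrix(plogis(-0.2), 2, 2), yr, 15,
                    pmf = function(n, l) dpois(n, l)),
    tolerance = 1e-10)
  expect_equal(
    nmixture_negloglik(c(0.3, -0.2, log(2)), yr, mixture = "NB", kmax = 15),
    oracle_nmix_nll(rep(exp(0.3), 2), matrix(plogis(-0.2), 2, 2), yr, 15,
                    pmf = function(n, l) dnbinom(n, size = 2, mu = l)),
    tolerance = 1e-10)
  pi0 <- plogis(0.4)
  expect_equal(
    nmixture_negloglik(c(0.3, -0.2, 0.4), yr, mixture = "ZIP", kmax = 15),
    oracle_nmix_nll(rep(exp(0.3), 2), matrix(plogis(-0.2), 2, 2), yr, 15,
                    pmf = function(n, l) ifelse(n == 0, pi0 + (1 - pi0) * dpois(0, l),
                                                (1 - pi0) * dpois(n, l))),
    tolerance = 1e-10)

  expect_error(nmixture_negloglik(c(0, 0), matrix(7, 1, 1), kmax = 5),
               class = "occumix_domain_error")
})

test_that("mixture families nest correctly at fixed coefficients", {
  d <- jersey_transects()
  y <- simulate_counts(d, seed = 13)
  par <- c(log(0.44), qlogis(0.33))
  base <- nmixture_negloglik(par, y, offset_km = d$transect_km, kmax = 50)
  # NB with dispersion -> infinity approaches Poisson
  expect_equal(nmixture_negloglik(c(par, log(1e8)), y, offset_km = d$transect_km,
                                  mixture = "NB", kmax = 50),
               base, tolerance = 1e-4)
  # ZIP with zero inflation -> 0 matches Poisson exactly
  expect_equal(nmixture_negloglik(c(par, -1e3), y, offset_km = d$transect_km,
                                  mixture = "ZIP", kmax = 50),
               base, tolerance = 1e-12)
})

test_that("truncation bound 50 is sufficient at the study scale", {
  d <- jersey_transects()
  y <- simulate_counts(d, seed = 17)
  f <- fit_nmixture(y, offset_km = d$transect_km, seed = 1)
  expect_true(f$converged)
  suff <- check_kmax(f)
  expect_true(suff)
  expect_lt(abs(attr(suff, "delta_nll")), 1e-6)
})

test_that("parameter counting follows the model structure", {
  d <- jersey_transects()
  y <- simulate_counts(d, seed = 23)
  fP <- fit_nmixture(y, offset_km = d$transect_km, seed = 1)
  fNB <- fit_nmixture(y, offset_km = d$transect_km, mixture = "NB", seed = 1)
  expect_identical(fP$npar, 2L)
  expect_identical(fNB$npar, 3L)
})

test_that("degenerate closed forms hold under perfect detection", {
  d <- generate_design(60, seed = 41)
  d$n_visits <- 1L
  y <- simulate_counts(d, b0 = log(2), alpha0 = qlogis(1 - 1e-9), offset = FALSE,
                       seed = 42)
  # single visit with p fixed at ~1: the profile MLE of lambda is the mean count
  p_fixed <- qlogis(1 - 1e-9)
  prof <- optimize(function(b) nmixture_negloglik(c(b, p_fixed), y, kmax = 50),
                   c(-3, 3), tol = 1e-9)
  expect_equal(exp(prof$minimum), mean(y[, 1]), tolerance = 1e-4)
  # and the posterior total equals the observed total
  f <- fit_nmixture(y, seed = 1, nstart = 2)
  f$coef[] <- c(log(mean(y[, 1])), p_fixed)
  f$converged <- TRUE   # coefficients are set analytically above
  expect_equal(sum(eb_posterior(f)$mean), sum(y[, 1]), tolerance = 1e-6)
})

test_that("empirical-Bayes posteriors are proper and match the Bayes table", {
  # worked single-site case: lambda = 1, p = 0.5, y = (1, 0), kmax = 10
  d <- tiny_design()[1, ]
  d$n_visits <- 2L; d$transect_km <- 1
  y <- matrix(c(1, 0), 1, 2)
  f <- fit_nmixture(y, offset_km = d$transect_km, seed = 1, kmax = 10, nstart = 1)
  f$coef[] <- c(log(1), qlogis(0.5))   # evaluate the posterior at fixed truth
  post <- eb_posterior(f)
  expect_equal(as.vector(attr(post, "posterior")),
               oracle_posterior(1, 0.5, c(1, 0), 10), tolerance = 1e-12)

  # general properties at the study scale
  dd <- jersey_transects()
  yy <- simulate_counts(dd, seed = 29)
  ff <- fit_nmixture(yy, offset_km = dd$transect_km, seed = 1)
  pp <- eb_posterior(ff)
  P <- attr(pp, "posterior")
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
  maxobs <- apply(yy, 1, max, na.rm = TRUE)
  # no posterior mass below the maximum observed count
  for (i in seq_len(nrow(yy))) {
    if (maxobs[i] > 0) expect_equal(sum(P[i, seq_len(maxobs[i])]), 0)
  }
  expect_true(all(pp$mean >= maxobs))
  expect_true(all(pp$lower <= pp$mode | pp$lower <= ceiling(pp$mean)))
  expect_true(all(pp$lower <= pp$upper))
})

test_that("posterior degenerates correctly in limiting cases", {
  d <- tiny_design()[1, ]; d$n_visits <- 1L; d$transect_km <- 1
  # perfect detection, y = 2 -> posterior point mass at N = 2
  y <- matrix(2, 1, 1)
  f <- fit_nmixture(y, seed = 1, kmax = 10, nstart = 1)
  f$coef[] <- c(log(1), qlogis(1 - 1e-12))
  post <- attr(eb_posterior(f), "posterior")
  expect_equal(unname(post[1, "2"]), 1, tolerance = 1e-9)
  # all-zero history with tiny lambda -> mass at 0
  y0 <- matrix(0, 1, 1)
  f0 <- fit_nmixture(y0, seed = 1, kmax = 10, nstart = 1) |> suppressWarnings()
  f0$coef[] <- c(log(1e-6), qlogis(0.5))
  expect_equal(unname(attr(eb_posterior(f0), "posterior")[1, "0"]), 1, tolerance = 1e-5)
})

test_that("minimum-known-alive raises only the lower bound", {
  expect_equal(raise_lower_bound(c(20, 169), 43), list(lower = 43, upper = 169))
  expect_equal(raise_lower_bound(c(20, 169), 10), list(lower = 20, upper = 169))
  expect_error(raise_lower_bound(c(20, 169), 200),
               class = "occumix_inconsistency_error")
})

test_that("abundance per km is invariant to rescaling transect lengths", {
  # doubling all lengths with the offset shifts total abundance, not density
  d <- generate_design(200, seed = 51)
  y <- simulate_counts(d, seed = 52)
  d2 <- d; d2$transect_km <- 2 * d$transect_km
  y2 <- simulate_counts(d2, seed = 52)
  f1 <- fit_nmixture(y, offset_km = d$transect_km, seed = 1, nstart = 3)
  f2 <- fit_nmixture(y2, offset_km = d2$transect_km, seed = 1, nstart = 3)
  se1 <- sqrt(f1$vcov[1, 1]); se2 <- sqrt(f2$vcov[1, 1])
  expect_lt(abs(f1$coef[[1]] - log(0.44)), 4 * se1)
  expect_lt(abs(f2$coef[[1]] - log(0.44)), 4 * se2)
})
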