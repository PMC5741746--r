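# One-tailed two-period power analysis for a proportional occupancy decline
# under imperfect detection: how many sites must be surveyed per period.

#' Asymptotic variance factor of the occupancy estimator
#'
#' Per-site variance factor of the MLE of occupancy under imperfect
#' detection with K surveys per site:
#' `v = psi * ((1 - psi) + (1 - p*) / (p* - K p (1 - p)^(K-1)))`
#' where `p* = 1 - (1-p)^K`, so that `Var(psi_hat) = v / S` across S sites.
#' At `p = 1` it reduces exactly to the binomial variance `psi (1 - psi)`.
#' The denominator `p* - K p (1-p)^(K-1)` must be positive for the design to
#' carry information about occupancy (it is, for any 0 < p < 1 and K >= 2).
#'
#' @param psi occupancy probability.
#' @param p per-survey detection probability.
#' @param K surveys per site.
#' @return the variance factor (vectorised over the arguments).
#' @export
occupancy_variance_factor <- function(psi, p, K) {
  .check_prob(psi, "psi", open_lower = TRUE, open_upper = TRUE)
  .check_prob(p, "p", open_lower = TRUE)
  if (any(K < 1 | K != round(K))) .validation_error("`K` must be a positive integer")
  pstar <- 1 - (1 - p)^K
  num <- 1 - pstar
  info <- pstar - K * p * (1 - p)^(K - 1)
  # info is 0 exactly at K = 1 (and at p = 1); guard against float residue
  degenerate <- info <= 1e-9 * pstar
  if (any(degenerate & num > 0)) {
    .stop("design carries no information about occupancy (p* <= K p (1-p)^(K-1))",
          "occumix_nonidentifiable_design_error")
  }
  ifelse(num == 0, psi * (1 - psi), psi * ((1 - psi) + num / info))
}

#' Sites required to detect an occupancy decline
#'
#' Two-period z-test design formula: with initial occupancy `psi1`, a
#' proportional decline `R` (so `psi2 = psi1 (1 - R)`), per-survey detection
#' `p` and `K` surveys per site in each period, the number of sites per
#' period for power `1 - beta` at one-tailed level `alpha` is
#' `S = ceiling( (z_{1-alpha} + z_{power})^2 (v1 + v2) / (psi1 - psi2)^2 )`
#' with `v_i` from [occupancy_variance_factor()]. Equal numbers of sites and
#' surveys are assumed in both periods.
#'
#' @param psi1 initial occupancy probability.
#' @param R proportional decline in (0, 1).
#' @param p per-survey detection probability.
#' @param K surveys per site.
#' @param alpha significance level (one-tailed by default, as for a decline
#'   alternative).
#' @param power target power.
#' @param two_tailed use `z_{1-alpha/2}` instead.
#' @return integer number of sites per period.
#' @export
sites_required <- function(psi1, R, p, K, alpha = 0.05, power = 0.8,
                           two_tailed = FALSE) {
  .check_prob(psi1, "psi1", open_lower = TRUE, open_upper = TRUE)
  if (R <= 0 || R >= 1) .stop("decline R must be in (0, 1): psi1 = psi2 needs infinitely many sites",
                              "occumix_infinite_sites_error")
  psi2 <- psi1 * (1 - R)
  z <- stats::qnorm(1 - if (two_tailed) alpha / 2 else alpha) + stats::qnorm(power)
  v1 <- occupancy_variance_factor(psi1, p, K)
  v2 <- occupancy_variance_factor(psi2, p, K)
  as.integer(ceiling(z^2 * (v1 + v2) / (psi1 - psi2)^2))
}

#' Power-analysis grid over survey effort, visits and decline size
#'
#' Evaluates [sites_required()] over a grid of ACO efforts (mapped to
#' detection through the fitted detection model), visit numbers and
#' proportional declines, with the initial occupancy taken from the fitted
#' occupancy model at a reference transect length. Interval bands for the
#' site numbers propagate the detection confidence-interval endpoints
#' (anti-monotone: the upper site bound comes from the lower detection
#' bound); the occupancy estimate is held at its point value. Grid cells
#' whose design carries no information are recorded as unattainable (NA)
#' rather than dropped.
#'
#' @param fit an `occu_fit` with an ACO detection covariate and a length
#'   offset on occupancy.
#' @param aco_grid ACO efforts (study grid: 0 to 100 by 10).
#' @param declines proportional declines R (study: 0.15, 0.30, 0.50).
#' @param visits surveys per site K (study: 4, 6, 8).
#' @param reference_km transect length at which the initial occupancy is
#'   evaluated (study: 1.5 km, the regional scheme's mean).
#' @param alpha,power,two_tailed see [sites_required()].
#' @param aco_name name of the ACO covariate.
#' @return a `power_grid` data frame: `acos`, `K`, `R`, `p`, `psi1`,
#'   `sites`, `sites_lower`, `sites_upper`, `attainable`.
#' @export
power_grid <- function(fit, aco_grid = seq(0, 100, 10),
                       declines = c(0.15, 0.30, 0.50), visits = c(4, 6, 8),
                       reference_km = 1.5, alpha = 0.05, power = 0.8,
                       two_tailed = FALSE, aco_name = "acos") {
  stopifnot(inherits(fit, "occu_fit"))
  nd <- stats::setNames(data.frame(aco_grid), aco_name)
  pd <- predict_detection(fit, newdata = nd)
  psi1 <- predict_occupancy(fit, reference_km)$estimate[1]
  cell <- function(p, R, K) {
    tryCatch(sites_required(psi1, R, p, K, alpha, power, two_tailed),
             occumix_nonidentifiable_design_error = function(e) NA_integer_,
             error = function(e) NA_integer_)
  }
  grid <- expand.grid(i = seq_along(aco_grid), K = visits, R = declines)
  out <- data.frame(
    acos = aco_grid[grid$i], K = grid$K, R = grid$R,
    p = pd$estimate[grid$i], psi1 = psi1,
    sites = mapply(cell, pd$estimate[grid$i], grid$R, grid$K),
    sites_lower = mapply(cell, pd$upper[grid$i], grid$R, grid$K),
    sites_upper = mapply(cell, pd$lower[grid$i], grid$R, grid$K))
  out$attainable <- !is.na(out$sites)
  structure(out, class = c("power_grid", "data.frame"))
}

#' Simulated power of the two-period occupancy decline test
#'
#' Monte-Carlo check of the design formula: for each replicate, detection
#' histories are simulated for `S` sites in each of two periods (occupancy
#' `psi1` and `psi1 (1 - R)`, constant detection `p`, `K` visits), a
#' constant occupancy model is fitted to each period by maximum likelihood,
#' and the one-tailed z statistic
#' `(psi1_hat - psi2_hat) / sqrt(v1_hat/S + v2_hat/S)` (variance factors
#' evaluated at the estimates) is compared against `z_{1-alpha}`. Returns
#' the rejection rate.
#'
#' @inheritParams sites_required
#' @param S sites per period.
#' @param n_reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return estimated power (rejection proportion across replicates).
#' @export
simulate_decline_power <- function(psi1, R, p, K, S, n_reps = 200,
                                   alpha = 0.05, seed = 1) {
  psi2 <- psi1 * (1 - R)
  zcrit <- stats::qnorm(1 - alpha)
  fit1 <- function(y) {
    opt <- stats::optim(c(0, 0), function(par) {
      psi <- invlogit(par[1]); pp <- invlogit(par[2])
      cond <- rowSums(ifelse(y == 1, log(pp), log(1 - pp)))
      lik <- psi * exp(cond) + (1 - psi) * (rowSums(y) == 0)
      if (any(lik <= 0)) return(1e10)
      -sum(log(lik))
    }, method = "BFGS", control = list(reltol = 1e-9))
    invlogit(opt$par)
  }
  .with_seed(seed, {
    mean(vapply(seq_len(n_reps), function(rep) {
      sim <- function(psi) {
        z <- stats::rbinom(S, 1, psi)
        matrix(stats::rbinom(S * K, 1, rep(z, K) * p), S, K)
      }
      est1 <- fit1(sim(psi1)); est2 <- fit1(sim(psi2))
      v1 <- occupancy_variance_factor(min(max(est1[1], 1e-6), 1 - 1e-6),
                                      min(max(est1[2], 1e-6), 1 - 1e-6), K) / S
      v2 <- occupancy_variance_factor(min(max(est2[1], 1e-6), 1 - 1e-6),
                                      min(max(est2[2], 1e-6), 1 - 1e-6), K) / S
      zstat <- (est1[1] - est2[1]) / sqrt(v1 + v2)
      as.numeric(zstat > zcrit)
    }, 0))
  })
}
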