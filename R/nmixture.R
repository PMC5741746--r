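# Binomial N-mixture model: latent site abundance N_i from a Poisson,
# negative-binomial or zero-inflated-Poisson mixture (log link, optional
# log-transect-length offset so the intercept is a per-km density) with visit
# counts as binomial thinnings of N_i (logit-link detection).

.mixtures <- c("P", "NB", "ZIP")

.n_extra <- function(mixture) switch(mixture, P = 0L, NB = 1L, ZIP = 1L)

# theta is carried on an unconstrained scale: log(size) for NB, logit of the
# zero-inflation probability for ZIP.
.mix_pmf <- function(n, lambda, mixture, theta) {
  switch(mixture,
    P = stats::dpois(n, lambda),
    NB = stats::dnbinom(n, size = exp(theta), mu = lambda),
    ZIP = {
      pi0 <- invlogit(theta)
      ifelse(n == 0, pi0 + (1 - pi0) * stats::dpois(0, lambda),
             (1 - pi0) * stats::dpois(n, lambda))
    })
}

.mix_mean <- function(lambda, mixture, theta) {
  switch(mixture, P = lambda, NB = lambda,
         ZIP = (1 - invlogit(theta)) * lambda)
}

.mix_var <- function(lambda, mixture, theta) {
  switch(mixture,
    P = lambda,
    NB = lambda + lambda^2 / exp(theta),
    ZIP = {
      pi0 <- invlogit(theta)
      (1 - pi0) * lambda * (1 + pi0 * lambda)
    })
}

.mix_rng <- function(n, lambda, mixture, theta) {
  switch(mixture,
    P = stats::rpois(n, lambda),
    NB = stats::rnbinom(n, size = exp(theta), mu = lambda),
    ZIP = stats::rpois(n, lambda) * (stats::runif(n) > invlogit(theta)))
}

#' Negative log-likelihood of the binomial N-mixture model
#'
#' Marginal likelihood per site-year, summing the latent abundance out up to
#' a truncation bound `kmax`:
#' `L_i = sum_{N=0}^{kmax} f(N; lambda_i, theta) prod_t Binom(y_it | N, p_it)`
#' with `log(lambda_i) = X_i b + log(L_i)` under the length offset. Missing
#' visits are skipped.
#'
#' @inheritParams occupancy_negloglik
#' @param y site-year x visit matrix of nonnegative integer counts.
#' @param mixture `"P"` (Poisson), `"NB"` (negative binomial) or `"ZIP"`
#'   (zero-inflated Poisson). NB/ZIP append one unconstrained parameter to
#'   `par`: `log(size)` or `logit(pi0)`.
#' @param kmax upper summation bound for the latent abundance (default 50,
#'   which the study found sufficient; must be at least the largest count).
#' @export
nmixture_negloglik <- function(par, y, site_covs = NULL, visit_covs = NULL,
                               det_covs = character(), state_covs = character(),
                               offset_km = NULL, mixture = c("P", "NB", "ZIP"),
                               kmax = 50) {
  mixture <- match.arg(mixture)
  y <- .check_count_matrix(y)
  if (max(y, na.rm = TRUE) > kmax) {
    .stop("`kmax` is below the largest observed count", "occumix_domain_error")
  }
  if (is.null(site_covs)) site_covs <- data.frame(row.names = seq_len(nrow(y)))
  mf <- .model_frame(y, site_covs, visit_covs, det_covs, state_covs, offset_km)
  extra <- .n_extra(mixture)
  if (length(par) != mf$r + mf$q + extra) {
    .stop(sprintf("expected %d parameters, got %d", mf$r + mf$q + extra, length(par)),
          "occumix_dimension_error")
  }
  .nmix_nll(par, mf, mixture, kmax)
}

.nmix_nll <- function(par, mf, mixture, kmax) {
  sp <- .split_par(par, mf, extra = .n_extra(mixture))
  lambda <- exp(drop(mf$Xs %*% sp$beta) + mf$offset)
  if (any(!is.finite(lambda))) return(1e10)
  p <- .det_prob_matrix(mf, sp$alpha)
  y <- mf$y
  nn <- 0:kmax
  ll <- 0
  for (i in seq_len(mf$n)) {
    g <- .mix_pmf(nn, lambda[i], mixture, sp$theta)
    for (t in mf$vis[[i]]) {
      g <- g * stats::dbinom(y[i, t], nn, p[i, t])
    }
    s <- sum(g)
    if (s <= 0 || !is.finite(s)) return(1e10)
    ll <- ll + log(s)
  }
  -ll
}

#' Fit a binomial N-mixture model
#'
#' Multi-start BFGS maximisation of the marginal likelihood; covariance from
#' the inverse observed information. NB dispersion and ZIP zero-inflation are
#' estimated on unconstrained scales (log size / logit pi0); a dispersion
#' estimate on the boundary (very large NB size) is flagged via
#' `boundary_dispersion` since that regime is known to be unstable.
#'
#' @inheritParams nmixture_negloglik
#' @inheritParams fit_occupancy
#' @return an `nmix_fit` with the same fields as an `occu_fit` plus
#'   `mixture`, `kmax`, `theta` and `boundary_dispersion`.
#' @export
fit_nmixture <- function(y, site_covs = NULL, visit_covs = NULL,
                         det_covs = character(), state_covs = character(),
                         offset_km = NULL, mixture = c("P", "NB", "ZIP"),
                         kmax = 50, nstart = 5, seed = 1, label = NULL) {
  mixture <- match.arg(mixture)
  y <- .check_count_matrix(y)
  if (sum(y, na.rm = TRUE) == 0) {
    warning("no nonzero counts; abundance is unidentified")
  }
  if (max(y, na.rm = TRUE) > kmax) {
    .stop("`kmax` is below the largest observed count", "occumix_domain_error")
  }
  if (is.null(site_covs)) site_covs <- data.frame(row.names = seq_len(nrow(y)))
  mf <- .model_frame(y, site_covs, visit_covs, det_covs, state_covs, offset_km)
  extra <- .n_extra(mixture)
  npar <- mf$r + mf$q + extra
  opt <- .ml_optim(function(par) .nmix_nll(par, mf, mixture, kmax),
                   npar, nstart, seed)
  cf <- opt$par
  names(cf) <- c(paste0("state:", colnames(mf$Xs)), paste0("det:", colnames(mf$Xd)),
                 if (extra) switch(mixture, NB = "log(size)", ZIP = "logit(pi0)"))
  dimnames(opt$vcov) <- list(names(cf), names(cf))
  theta <- if (extra) unname(cf[npar]) else numeric(0)
  structure(list(
    coef = cf, vcov = opt$vcov, loglik = -opt$value, npar = npar,
    converged = opt$converged, mf = mf, mixture = mixture, kmax = kmax,
    theta = theta,
    boundary_dispersion = mixture == "NB" && length(theta) && theta > log(1e4),
    det_covs = det_covs, state_covs = state_covs,
    offset_km = offset_km, scaling = attr(site_covs, "scaling"),
    site_covs = site_covs, visit_covs = visit_covs,
    label = label %||% .model_label("lambda", state_covs, det_covs, mixture)
  ), class = "nmix_fit")
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat("N-mixture model:", x$label,
      if (!is.null(x$offset_km)) "+ log(length) offset" else "", "\n")
  cat(sprintf("  logLik %.3f, npar %d, kmax %d, converged: %s\n",
              x$loglik, x$npar, x$kmax, x$converged))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
logLik.nmix_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
coef.nmix_fit <- function(object, ...) object$coef

#' @export
vcov.nmix_fit <- function(object, ...) object$vcov

.fitted_lambda <- function(fit) {
  exp(drop(fit$mf$Xs %*% fit$coef[seq_len(fit$mf$r)]) + fit$mf$offset)
}

.fitted_p <- function(fit) {
  .det_prob_matrix(fit$mf, fit$coef[fit$mf$r + seq_len(fit$mf$q)])
}

#' Check that the abundance truncation bound is sufficient
#'
#' Re-evaluates the negative log-likelihood at the fitted parameters with the
#' bound doubled; a change below `tol` indicates the truncation at `kmax`
#' does not affect the fit.
#'
#' @param fit an `nmix_fit`.
#' @param tol tolerance on the change in negative log-likelihood.
#' @return logical, with the observed change as attribute `delta_nll`.
#' @export
check_kmax <- function(fit, tol = 1e-6) {
  nll1 <- .nmix_nll(unname(fit$coef), fit$mf, fit$mixture, fit$kmax)
  nll2 <- .nmix_nll(unname(fit$coef), fit$mf, fit$mixture, 2 * fit$kmax)
  structure(abs(nll1 - nll2) < tol, delta_nll = nll1 - nll2)
}

#' Empirical-Bayes posterior abundance per site-year
#'
#' Posterior of the latent abundance given each site's counts and the fitted
#' parameters: `P(N_i = n | y_i) propto f(n; lambda_i, theta)
#' prod_t Binom(y_it | n, p_it)`, normalised over `0..kmax`. The point
#' summary (best unbiased predictor) is the posterior mean; the interval is
#' the central 95% integer interval of the posterior.
#'
#' @param fit a converged `nmix_fit`.
#' @param level central posterior interval mass.
#' @return an `eb_posterior` data frame (`site_year`, `mean`, `mode`,
#'   `lower`, `upper`) with the full posterior matrix (site-years x
#'   `0:kmax`) as attribute `posterior`.
#' @export
eb_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (!fit$converged) warning("fit did not converge; posteriors may be unreliable")
  lambda <- .fitted_lambda(fit)
  p <- .fitted_p(fit)
  y <- fit$mf$y
  nn <- 0:fit$kmax
  post <- matrix(NA_real_, fit$mf$n, fit$kmax + 1,
                 dimnames = list(rownames(y), nn))
  for (i in seq_len(fit$mf$n)) {
    g <- .mix_pmf(nn, lambda[i], fit$mixture, fit$theta)
    for (t in which(!is.na(y[i, ]))) {
      g <- g * stats::dbinom(y[i, t], nn, p[i, t])
    }
    post[i, ] <- g / sum(g)
  }
  cdf <- t(apply(post, 1, cumsum))
  a <- (1 - level) / 2
  out <- data.frame(
    site_year = rownames(y) %||% as.character(seq_len(nrow(y))),
    mean = drop(post %*% nn),
    mode = nn[apply(post, 1, which.max)],
    lower = apply(cdf, 1, function(f) nn[which(f >= a)[1]]),
    upper = apply(cdf, 1, function(f) nn[which(f >= 1 - a)[1]]),
    row.names = NULL)
  structure(out, posterior = post, class = c("eb_posterior", "data.frame"))
}

#' Total abundance across transects with a parametric-bootstrap interval
#'
#' Point estimate: the sum of per-site posterior-mean abundances under the
#' fitted model. Interval: parametric bootstrap — simulate count matrices
#' from the fitted model, refit (warm-started at the original estimates),
#' and take percentiles of the re-summed posterior means. Refits that fail
#' are dropped and counted; more than 10% failures triggers a warning.
#'
#' @param fit a converged `nmix_fit`.
#' @param n_boot number of bootstrap simulations (the study used 1000).
#' @param seed integer seed driving the full bootstrap chain.
#' @param level interval level.
#' @return list with `estimate`, `lower`, `upper`, `level`, `n_boot`,
#'   `n_failed`, and the bootstrap totals in `boot`.
#' @export
total_abundance <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (!fit$converged) .validation_error("total_abundance requires a converged fit")
  est <- sum(eb_posterior(fit)$mean)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ysim <- .simulate_nmix(fit)
      refit <- tryCatch(.refit(fit, ysim), error = function(e) NULL)
      if (is.null(refit) || !refit$converged) return(NA_real_)
      sum(eb_posterior(refit)$mean)
    }, 0)
  })
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  }
  a <- (1 - level) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], level = level,
       n_boot = n_boot, n_failed = n_failed, boot = boot)
}

#' Raise an abundance lower bound with a minimum known alive
#'
#' When individual identification establishes a minimum number of animals
#' alive, the lower confidence bound of total abundance can be raised to that
#' number. The upper bound is untouched; a minimum exceeding the upper bound
#' is inconsistent and errors.
#'
#' @param interval either the result of [total_abundance()] or a numeric
#'   `c(lower, upper)`.
#' @param minimum_known_alive nonnegative integer.
#' @return the interval with `lower = max(lower, minimum_known_alive)`.
#' @export
raise_lower_bound <- function(interval, minimum_known_alive) {
  stopifnot(minimum_known_alive >= 0)
  if (is.numeric(interval) && length(interval) == 2) {
    interval <- list(lower = interval[1], upper = interval[2])
  }
  if (minimum_known_alive > interval$upper) {
    .stop("minimum known alive exceeds the interval's upper bound",
          "occumix_inconsistency_error")
  }
  interval$lower <- max(interval$lower, minimum_known_alive)
  interval
}

# Simulate a count matrix from a fitted N-mixture model (NA pattern kept).
.simulate_nmix <- function(fit) {
  lambda <- .fitted_lambda(fit)
  p <- .fitted_p(fit)
  y <- fit$mf$y
  N <- .mix_rng(fit$mf$n, lambda, fit$mixture, fit$theta)
  ysim <- matrix(NA_real_, nrow(y), ncol(y), dimnames = dimnames(y))
  obs <- !is.na(y)
  ysim[obs] <- stats::rbinom(sum(obs), rep(N, ncol(y))[obs], p[obs])
  ysim
}

# Simulate a detection history from a fitted occupancy model.
.simulate_occu <- function(fit) {
  psi <- invlogit(drop(fit$mf$Xs %*% fit$coef[seq_len(fit$mf$r)]) + fit$mf$offset)
  p <- .fitted_p(fit)
  y <- fit$mf$y
  z <- stats::rbinom(fit$mf$n, 1, psi)
  ysim <- matrix(NA_real_, nrow(y), ncol(y), dimnames = dimnames(y))
  obs <- !is.na(y)
  ysim[obs] <- stats::rbinom(sum(obs), 1, (rep(z, ncol(y)) * p)[obs])
  ysim
}

# Warm-started single-start refit on new data, same model structure. The
# covariance matrix is not recomputed (bootstrap consumers only need the
# point estimates and the convergence flag).
.refit <- function(fit, ynew) {
  mf <- fit$mf
  mf$y <- ynew
  mf <- .index_frame(mf)
  if (inherits(fit, "nmix_fit")) {
    opt <- .ml_optim(function(par) .nmix_nll(par, mf, fit$mixture, fit$kmax),
                     fit$npar, nstart = 1, start = unname(fit$coef),
                     hessian = FALSE)
  } else {
    opt <- .ml_optim(function(par) .occu_nll(par, mf),
                     fit$npar, nstart = 1, start = unname(fit$coef),
                     hessian = FALSE)
  }
  out <- fit
  out$coef[] <- opt$par
  out$vcov[] <- opt$vcov
  out$loglik <- -opt$value
  out$converged <- opt$converged
  out$mf <- mf
  out
}
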