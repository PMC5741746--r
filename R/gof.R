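# Pearson chi-square goodness of fit with a parametric-bootstrap null
# distribution, and the overdispersion ratio c-hat.

#' Pearson chi-square statistic of a fitted model
#'
#' Cell-level statistic over non-missing site x visit observations:
#' `sum (y_it - e_it)^2 / v_it` with fitted mean and variance under the
#' model. Occupancy: `e = psi_i p_it` with Bernoulli variance `e(1-e)`.
#' N-mixture: `e = E[N_i] p_it` with the marginal count variance
#' `p(1-p) E[N] + p^2 Var[N]` of the chosen mixture. A zero fitted variance
#' against a nonzero residual yields `Inf`.
#'
#' @param fit a converged `occu_fit` or `nmix_fit`.
#' @return the observed statistic.
#' @export
pearson_chi2 <- function(fit) UseMethod("pearson_chi2")

#' @export
pearson_chi2.occu_fit <- function(fit) {
  psi <- invlogit(drop(fit$mf$Xs %*% fit$coef[seq_len(fit$mf$r)]) + fit$mf$offset)
  p <- .fitted_p(fit)
  e <- psi * p
  .chi2_cells(fit$mf$y, e, e * (1 - e))
}

#' @export
pearson_chi2.nmix_fit <- function(fit) {
  lambda <- .fitted_lambda(fit)
  p <- .fitted_p(fit)
  EN <- .mix_mean(lambda, fit$mixture, fit$theta)
  VN <- .mix_var(lambda, fit$mixture, fit$theta)
  e <- EN * p
  v <- p * (1 - p) * EN + p^2 * VN
  .chi2_cells(fit$mf$y, e, v)
}

.chi2_cells <- function(y, e, v) {
  obs <- !is.na(y)
  r2 <- (y[obs] - e[obs])^2
  v <- v[obs]
  if (any(v == 0 & r2 > 0)) return(Inf)
  sum((r2 / v)[v > 0])
}

#' Parametric-bootstrap goodness of fit
#'
#' Simulates `n_sim` datasets from the fitted model, refits each
#' (warm-started), and recomputes the Pearson statistic, giving the null
#' distribution of the statistic under the model. The p-value is the
#' proportion of simulated statistics at least as large as the observed one;
#' the overdispersion ratio is `chat = observed / mean(simulated)`. Failed
#' refits are dropped and counted.
#'
#' @param fit a converged `occu_fit` or `nmix_fit`.
#' @param n_sim number of bootstrap simulations (the study used 1000).
#' @param seed integer seed for the simulation chain.
#' @return a `gof_result` list: `statistic`, `p_value`, `chat`, `boot_mean`,
#'   `n_sim`, `n_failed`, and the simulated statistics in `boot`.
#' @export
bootstrap_gof <- function(fit, n_sim = 1000, seed = 1) {
  stopifnot(inherits(fit, c("occu_fit", "nmix_fit")))
  if (n_sim < 1) .validation_error("`n_sim` must be at least 1")
  if (!fit$converged) .validation_error("bootstrap_gof requires a converged fit")
  obs <- pearson_chi2(fit)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      ysim <- if (inherits(fit, "nmix_fit")) .simulate_nmix(fit) else .simulate_occu(fit)
      refit <- tryCatch(.refit(fit, ysim), error = function(e) NULL)
      if (is.null(refit) || !refit$converged) return(NA_real_)
      pearson_chi2(refit)
    }, 0)
  })
  ok <- is.finite(boot)
  structure(list(statistic = obs,
                 p_value = mean(boot[ok] >= obs),
                 chat = obs / mean(boot[ok]),
                 boot_mean = mean(boot[ok]),
                 n_sim = n_sim, n_failed = sum(!ok), boot = boot),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Parametric-bootstrap GOF: chi2 = %.2f, p = %.3f, c-hat = %.2f (%d sims, %d failed)\n",
              x$statistic, x$p_value, x$chat, x$n_sim, x$n_failed))
  invisible(x)
}
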