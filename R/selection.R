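# Information-theoretic model selection: AICc / QAICc and Akaike weights.

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`. The effective number of
#' observations `n_obs` is a modelling choice: for this workflow the study
#' convention is the total number of surveys (132) when ranking detection
#' structures and the number of site-years (19) for occupancy and abundance
#' structures.
#'
#' @param loglik maximised log-likelihood.
#' @param k_par number of estimated parameters.
#' @param n_obs effective number of observations; must exceed `k_par + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k_par, n_obs) {
  if (n_obs <= k_par + 1) {
    .stop("AICc small-sample correction undefined: n_obs <= k_par + 1",
          "occumix_undefined_correction_error")
  }
  -2 * loglik + 2 * k_par + 2 * k_par * (k_par + 1) / (n_obs - k_par - 1)
}

#' Quasi-likelihood AICc under overdispersion
#'
#' `QAICc = -2 logLik / chat + 2k' + 2k'(k'+1)/(n - k' - 1)` where
#' `k' = k_par + 1` counts the estimated overdispersion ratio as a parameter
#' (so a constant-detection, constant-abundance model is booked with 3
#' parameters). `chat` below 1 indicates underdispersion and is clamped to 1
#' with a message, in which case QAICc reduces to AICc with the extra
#' parameter slot.
#'
#' @inheritParams aicc
#' @param chat overdispersion ratio (observed / expected goodness-of-fit
#'   statistic), typically taken from the most complex candidate model.
#' @export
qaicc <- function(loglik, k_par, n_obs, chat) {
  if (!is.finite(chat) || chat <= 0) .validation_error("`chat` must be positive")
  if (chat < 1) {
    message("chat < 1 (underdispersion); clamped to 1")
    chat <- 1
  }
  kq <- k_par + 1
  if (n_obs <= kq + 1) {
    .stop("QAICc small-sample correction undefined: n_obs <= k_par + 2",
          "occumix_undefined_correction_error")
  }
  -2 * loglik / chat + 2 * kq + 2 * kq * (kq + 1) / (n_obs - kq - 1)
}

#' Rank candidate models by AICc or QAICc
#'
#' Builds the model-selection table: criterion value per model, delta to the
#' best model, and Akaike weights `exp(-delta/2) / sum`. Non-converged fits
#' are discarded with a message. With `chat` supplied the quasi-likelihood
#' criterion is used (one parameter added per model for the c-hat slot).
#' Ties in the criterion are ordered by fewer parameters.
#'
#' @param fits named list of `occu_fit` / `nmix_fit` objects (or bare lists
#'   with `loglik`, `npar`, `converged`, `label`).
#' @param n_obs effective number of observations (see [aicc()]).
#' @param chat optional overdispersion ratio; switches to QAICc.
#' @return a `model_table` data frame sorted by the criterion: `model`, `k`,
#'   `criterion`, `value`, `delta`, `weight`, `loglik`.
#' @export
rank_models <- function(fits, n_obs, chat = NULL) {
  if (!length(fits)) .validation_error("empty candidate set")
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$label %||% "model", "")
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (any(!conv)) {
    message("discarding model(s) that failed to converge: ",
            paste(names(fits)[!conv], collapse = ", "))
    fits <- fits[conv]
  }
  if (!length(fits)) .validation_error("no converged candidate models")
  ll <- vapply(fits, function(f) f$loglik, 0)
  k <- vapply(fits, function(f) f$npar, 0L)
  if (is.null(chat)) {
    val <- mapply(aicc, ll, k, MoreArgs = list(n_obs = n_obs))
    crit <- "AICc"
    k_shown <- k
  } else {
    val <- mapply(qaicc, ll, k, MoreArgs = list(n_obs = n_obs, chat = chat))
    crit <- "QAICc"
    k_shown <- k + 1L   # c-hat bookkeeping slot
  }
  ord <- order(val, k_shown)
  val <- val[ord]; ll <- ll[ord]; k_shown <- k_shown[ord]
  delta <- val - val[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(data.frame(model = names(fits)[ord], k = k_shown, criterion = crit,
                       value = val, delta = delta, weight = w, loglik = ll,
                       row.names = NULL),
            class = c("model_table", "data.frame"))
}
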