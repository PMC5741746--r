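# Seeded synthetic-data generator emulating the study design: 19 site-years,
# 3-8 visits, skewed ACO effort (6-436) and transect lengths (0.28-19.1 km),
# four habitat classes; Bernoulli detection histories and Poisson/NB/ZIP
# count matrices with the hierarchical structure the models assume.

#' Generate a synthetic survey design
#'
#' Samples site-year records by resampling whole rows (visit number, ACO
#' count, transect length, habitat, area) from a template design with
#' replacement, which preserves the joint skew of effort and transect length
#' observed in the study. Defaults to the packaged 19-site-year fixture as
#' template.
#'
#' @param n_sites number of site-years (default: the study's 19).
#' @param seed mandatory integer seed.
#' @param template a `survey_design` to resample from.
#' @return a `survey_design` data frame with `n_sites` rows.
#' @export
generate_design <- function(n_sites = 19, seed, template = jersey_transects()) {
  if (missing(seed)) .validation_error("`seed` is mandatory for reproducibility")
  if (!is.numeric(n_sites) || n_sites < 1) {
    .stop("`n_sites` must be a positive integer", "occumix_config_error")
  }
  template <- as.data.frame(template)
  rows <- .with_seed(seed, sample.int(nrow(template), n_sites, replace = TRUE))
  out <- template[rows, c("habitat", "area_ha", "n_visits", "acos", "transect_km")]
  out <- data.frame(site = sprintf("S%02d", seq_len(n_sites)), year = 1L, out,
                    stringsAsFactors = FALSE)
  out$habitat <- as.character(out$habitat)
  .validate_design(out)
}

#' Study-calibrated detection coefficients on the raw ACO scale
#'
#' Logit-linear detection in ACO effort anchored at the study's two reported
#' operating points: p = 0.19 at 10 ACOs (the regional scheme's effort) and
#' p = 0.33 at 95 ACOs (the study's mean effort per site). Used as the
#' generator's default ACO-dependent detection truth.
#'
#' @return named vector `c(intercept, slope)` on the logit scale per raw ACO.
#' @export
study_detection_coefs <- function() {
  slope <- (logit(0.33) - logit(0.19)) / (95 - 10)
  c(intercept = unname(logit(0.19) - 10 * slope), slope = unname(slope))
}

.sim_p_matrix <- function(design, alpha0, alpha, tmax) {
  n <- nrow(design)
  eta <- matrix(alpha0, n, tmax)
  if (!is.null(alpha)) {
    for (nm in names(alpha)) {
      if (!nm %in% names(design)) .schema_error(sprintf("unknown covariate `%s`", nm))
      eta <- eta + alpha[nm] * design[[nm]]   # site-level, recycled over visits
    }
  }
  invlogit(eta)
}

.sim_mask <- function(design, m) {
  tmax <- ncol(m)
  for (i in seq_len(nrow(m))) {
    if (design$n_visits[i] < tmax) m[i, (design$n_visits[i] + 1):tmax] <- NA
  }
  rownames(m) <- rownames(design)
  colnames(m) <- paste0("v", seq_len(tmax))
  m
}

#' Simulate detection/non-detection histories
#'
#' Hierarchical generation under the single-season occupancy model:
#' `z_i ~ Bernoulli(psi_i)` with
#' `logit(psi_i) = beta0 + beta z_i + log(L_i)` (offset on by default), then
#' `y_it | z_i ~ Bernoulli(z_i p_it)`. Visits beyond each site-year's
#' `n_visits` are missing. Defaults are the study conditions: per-km
#' occupancy 0.44 and constant detection 0.33.
#'
#' @param design a `survey_design`.
#' @param beta0 occupancy intercept, logit scale (per km when `offset`).
#' @param beta optional named vector of occupancy slopes over raw design
#'   columns.
#' @param alpha0 detection intercept, logit scale.
#' @param alpha optional named vector of detection slopes over raw design
#'   columns (e.g. [study_detection_coefs()] for ACO-driven detection).
#' @param offset include the log-transect-length offset on occupancy.
#' @param seed mandatory integer seed.
#' @return a 0/1 detection matrix (`n_sites` x `max(n_visits)`, NA-padded)
#'   with the latent occupancy states as attribute `z`.
#' @export
simulate_occupancy_history <- function(design, beta0 = logit(0.44), beta = NULL,
                                       alpha0 = logit(0.33), alpha = NULL,
                                       offset = TRUE, seed) {
  if (missing(seed)) .validation_error("`seed` is mandatory for reproducibility")
  design <- .validate_design(as.data.frame(design))
  n <- nrow(design); tmax <- max(design$n_visits)
  eta <- rep(beta0, n)
  if (!is.null(beta)) for (nm in names(beta)) eta <- eta + beta[nm] * design[[nm]]
  if (offset) eta <- eta + log(design$transect_km)
  psi <- invlogit(eta)
  .with_seed(seed, {
    z <- stats::rbinom(n, 1, psi)
    p <- .sim_p_matrix(design, alpha0, alpha, tmax)
    y <- matrix(stats::rbinom(n * tmax, 1, rep(z, tmax) * p), n, tmax)
    structure(.sim_mask(design, y), z = z)
  })
}

#' Simulate repeat-count matrices
#'
#' Generation under the binomial N-mixture model with closure: one latent
#' abundance per site-year, `N_i ~ mixture(lambda_i, theta)` with
#' `log(lambda_i) = b0 + b z_i + log(L_i)` (offset on by default), and
#' `y_it | N_i ~ Binomial(N_i, p_it a)` where `a` is a per-visit availability
#' (1 by default; values below 1 emulate temporary emigration, a controlled
#' closure violation). Defaults are the study conditions: 0.44 snakes per km
#' and constant detection 0.33.
#'
#' @inheritParams simulate_occupancy_history
#' @param b0 log abundance intercept (per km when `offset`).
#' @param b optional named abundance slopes over raw design columns.
#' @param mixture `"P"`, `"NB"` or `"ZIP"`.
#' @param theta unconstrained mixture parameter (NB: log size; ZIP:
#'   logit zero-inflation).
#' @param availability per-visit availability in (0, 1]; below 1 breaks the
#'   closure assumption deliberately.
#' @return a count matrix with the latent abundances as attribute `N`.
#' @export
simulate_counts <- function(design, b0 = log(0.44), b = NULL,
                            alpha0 = logit(0.33), alpha = NULL,
                            mixture = c("P", "NB", "ZIP"), theta = numeric(0),
                            offset = TRUE, availability = 1, seed) {
  if (missing(seed)) .validation_error("`seed` is mandatory for reproducibility")
  mixture <- match.arg(mixture)
  if (.n_extra(mixture) && !length(theta)) {
    .stop(sprintf("mixture `%s` needs a `theta` parameter", mixture),
          "occumix_config_error")
  }
  stopifnot(availability > 0, availability <= 1)
  design <- .validate_design(as.data.frame(design))
  n <- nrow(design); tmax <- max(design$n_visits)
  eta <- rep(b0, n)
  if (!is.null(b)) for (nm in names(b)) eta <- eta + b[nm] * design[[nm]]
  if (offset) eta <- eta + log(design$transect_km)
  lambda <- exp(eta)
  .with_seed(seed, {
    N <- .mix_rng(n, lambda, mixture, theta)
    p <- .sim_p_matrix(design, alpha0, alpha, tmax) * availability
    y <- matrix(stats::rbinom(n * tmax, rep(N, tmax), p), n, tmax)
    structure(.sim_mask(design, y), N = N)
  })
}
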