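# Confidence-of-absence calculators: cumulative detection probability over
# repeat surveys and the minimum number of surveys for a target confidence.

#' Cumulative detection probability over K surveys
#'
#' `p* = 1 - (1 - p)^K`: the probability of at least one detection in K
#' independent surveys of an occupied site with per-survey detectability p.
#'
#' @param p per-survey detection probability.
#' @param K nonnegative integer number of surveys.
#' @export
cumulative_detection <- function(p, K) {
  .check_prob(p, "p")
  if (any(K < 0 | K != round(K))) .validation_error("`K` must be a nonnegative integer")
  1 - (1 - p)^K
}

#' Minimum surveys for a target confidence of absence
#'
#' Smallest integer K with `1 - (1-p)^K >= confidence`, i.e. the number of
#' blank surveys after which absence can be declared with the target
#' confidence. Computed as `ceiling(log(1-confidence)/log(1-p))` and then
#' verified against the defining inequality to guard against floating-point
#' edge cases.
#'
#' @param p per-survey detection probability in (0, 1\].
#' @param confidence target confidence in (0, 1).
#' @return integer number of surveys (vectorised over `p` and `confidence`,
#'   recycled to a common length).
#' @export
min_surveys <- function(p, confidence) {
  .check_prob(confidence, "confidence", open_lower = TRUE, open_upper = TRUE)
  if (any(p <= 0)) {
    .stop("confidence unreachable: per-survey detection is 0",
          "occumix_unreachable_confidence_error")
  }
  .check_prob(p, "p")
  m <- max(length(p), length(confidence))
  p <- rep_len(p, m); confidence <- rep_len(confidence, m)
  mapply(function(pi, conf) {
    if (pi >= 1) return(1L)
    K <- as.integer(ceiling(log1p(-conf) / log1p(-pi)))
    while (K > 1 && cumulative_detection(pi, K - 1) >= conf) K <- K - 1L
    while (cumulative_detection(pi, K) < conf) K <- K + 1L
    K
  }, p, confidence, USE.NAMES = FALSE)
}

#' Survey-effort curve: detection and required surveys across ACO effort
#'
#' Maps a grid of ACO counts through a fitted detection model to per-survey
#' detection probabilities (with confidence intervals), then through
#' [min_surveys()] to the minimum surveys required at each target confidence.
#' The interval band for the required surveys is anti-monotone in the
#' detection band: the upper survey bound comes from the lower detection
#' bound and vice versa.
#'
#' @param fit an `occu_fit` whose detection model includes the ACO covariate
#'   (with stored scaling so raw ACO counts can be projected).
#' @param aco_grid integer grid of ACO counts (the study plotted 0-500;
#'   values beyond the training range are flagged with a warning).
#' @param confidences target confidences (study levels: 0.80, 0.90, 0.95).
#' @param aco_name name of the ACO covariate in the fit.
#' @return an `effort_curve` data frame in long format: `acos`, `p`,
#'   `p_lower`, `p_upper`, `confidence`, `K`, `K_lower`, `K_upper`.
#' @export
effort_curve <- function(fit, aco_grid = 0:500, confidences = c(0.80, 0.90, 0.95),
                         aco_name = "acos") {
  stopifnot(inherits(fit, "occu_fit"))
  if (!aco_name %in% fit$det_covs) {
    .schema_error(sprintf("fit has no detection covariate `%s`", aco_name))
  }
  if (!is.null(fit$scaling)) {
    i <- match(aco_name, fit$scaling$covariate)
    if (!is.na(i)) {
      rng <- fit$scaling$mean[i] + c(-1, 1) * 2.5 * fit$scaling$sd[i]
      if (any(aco_grid > rng[2] | aco_grid < max(0, rng[1]))) {
        warning("ACO grid extends beyond the observed effort range; extrapolating")
      }
    }
  }
  nd <- stats::setNames(data.frame(aco_grid), aco_name)
  pd <- predict_detection(fit, newdata = nd)
  out <- do.call(rbind, lapply(confidences, function(conf) {
    data.frame(acos = aco_grid,
               p = pd$estimate, p_lower = pd$lower, p_upper = pd$upper,
               confidence = conf,
               K = min_surveys(pd$estimate, conf),
               K_lower = min_surveys(pd$upper, conf),
               K_upper = min_surveys(pd$lower, conf))
  }))
  structure(out, class = c("effort_curve", "data.frame"))
}
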