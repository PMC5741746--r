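# Internal helpers shared across modules.

logit <- stats::qlogis
invlogit <- stats::plogis

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "occumix_error")))
}

.schema_error <- function(msg) .stop(msg, "occumix_schema_error")
.validation_error <- function(msg) .stop(msg, "occumix_validation_error")

.check_prob <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  if (any(!is.finite(x)) ||
      any(if (open_lower) x <= 0 else x < 0) ||
      any(if (open_upper) x >= 1 else x > 1)) {
    .validation_error(sprintf("`%s` must be a probability in %s0, 1%s",
                              name,
                              if (open_lower) "(" else "[",
                              if (open_upper) ")" else "]"))
  }
  invisible(x)
}

.check_count_matrix <- function(y) {
  if (!is.matrix(y)) y <- as.matrix(y)
  if (!is.numeric(y)) .validation_error("count matrix must be numeric")
  vals <- y[!is.na(y)]
  if (any(vals < 0)) .validation_error("counts must be nonnegative")
  if (any(vals != round(vals))) .validation_error("counts must be integers")
  y
}

# Run `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so fits don't perturb user simulations.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Quasi-Newton maximisation with a zero start plus seeded random restarts;
# objective convergence tolerance 1e-8. Returns the best converged solution
# (or the best attempt, flagged).
.ml_optim <- function(nll, npar, nstart = 5, seed = NULL, start = NULL,
                      hessian = TRUE) {
  starts <- matrix(0, nstart, npar)
  if (!is.null(start)) starts[1, ] <- start
  if (nstart > 1) {
    starts[-1, ] <- .with_seed(seed, matrix(stats::rnorm((nstart - 1) * npar, 0, 0.75),
                                            nstart - 1, npar))
    if (!is.null(start)) starts[-1, ] <- sweep(starts[-1, , drop = FALSE], 2, start, `+`)
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    opt <- tryCatch(
      stats::optim(starts[s, ], nll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) ||
        (opt$convergence == 0 && best$convergence != 0) ||
        (opt$convergence == best$convergence && opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) return(list(par = rep(NA_real_, npar), value = NA_real_,
                                 converged = FALSE, vcov = matrix(NA_real_, npar, npar)))
  V <- NULL
  if (hessian) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  }
  ok_vcov <- !is.null(V) && all(is.finite(V)) && all(diag(V) > 0)
  list(par = best$par, value = best$value,
       converged = best$convergence == 0,
       vcov = if (ok_vcov) V else matrix(NA_real_, npar, npar))
}

.fmt_ci <- function(est, lo, hi, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"), est, lo, hi)
}
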