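# Internal design-matrix construction shared by the occupancy and N-mixture
# likelihoods. Detection covariates may live at the site level (recycled over
# visits) or at the visit level (a site x visit matrix per covariate).

.build_state_design <- function(site_covs, covs) {
  n <- nrow(site_covs)
  if (!length(covs)) {
    return(matrix(1, n, 1, dimnames = list(rownames(site_covs), "(Intercept)")))
  }
  missing <- setdiff(covs, names(site_covs))
  if (length(missing)) {
    .schema_error(paste0("unknown site covariate(s): ", paste(missing, collapse = ", ")))
  }
  df <- site_covs[, covs, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  if (any(!is.finite(as.matrix(df[num])))) .validation_error("non-finite site covariate")
  stats::model.matrix(stats::reformulate(covs), data = df)
}

.build_det_design <- function(y, site_covs, visit_covs, covs) {
  n <- nrow(y); tmax <- ncol(y)
  if (!length(covs)) {
    return(matrix(1, n * tmax, 1, dimnames = list(NULL, "(Intercept)")))
  }
  long <- lapply(covs, function(nm) {
    if (!is.null(visit_covs) && nm %in% names(visit_covs)) {
      v <- visit_covs[[nm]]
      stopifnot(nrow(v) == n, ncol(v) == tmax)
      as.vector(v)                       # column-major: visit t block holds all sites
    } else if (nm %in% names(site_covs)) {
      rep(site_covs[[nm]], times = tmax)
    } else {
      .schema_error(sprintf("unknown detection covariate `%s`", nm))
    }
  })
  names(long) <- covs
  df <- as.data.frame(long)
  # Covariate cells at missing visits never enter the likelihood; backfill so
  # model.matrix keeps the row count.
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      if (any(!is.finite(df[[nm]][!is.na(as.vector(y))]))) {
        .validation_error(sprintf("non-finite detection covariate `%s`", nm))
      }
      df[[nm]][is.na(df[[nm]])] <- 0
    } else {
      df[[nm]] <- as.factor(df[[nm]])
      df[[nm]][is.na(df[[nm]])] <- levels(df[[nm]])[1]
    }
  }
  stats::model.matrix(stats::reformulate(covs), data = df)
}

# Assemble the pieces both fitters need.
.model_frame <- function(y, site_covs, visit_covs, det_covs, state_covs, offset_km) {
  n <- nrow(y)
  Xd <- .build_det_design(y, site_covs, visit_covs, det_covs)
  Xs <- .build_state_design(site_covs, state_covs)
  off <- if (is.null(offset_km)) rep(0, n) else {
    if (any(offset_km <= 0)) .validation_error("transect lengths must be positive")
    log(offset_km)
  }
  mf <- list(y = y, Xd = Xd, Xs = Xs, offset = off,
             q = ncol(Xd), r = ncol(Xs), n = n, tmax = ncol(y))
  .index_frame(mf)
}

# Precompute missingness masks reused on every likelihood evaluation; must be
# refreshed whenever mf$y is replaced (warm refits on simulated data).
.index_frame <- function(mf) {
  mf$miss <- is.na(mf$y)
  mf$vis <- lapply(seq_len(mf$n), function(i) which(!mf$miss[i, ]))
  det <- mf$y == 1
  det[mf$miss] <- FALSE
  mf$no_det <- .rowSums(det, mf$n, mf$tmax) == 0
  mf
}

.split_par <- function(par, mf, extra = 0) {
  list(beta = par[seq_len(mf$r)],
       alpha = par[mf$r + seq_len(mf$q)],
       theta = if (extra) par[mf$r + mf$q + seq_len(extra)] else numeric(0))
}

.det_prob_matrix <- function(mf, alpha) {
  eta <- drop(mf$Xd %*% alpha)
  matrix(invlogit(eta), mf$n, mf$tmax)
}
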