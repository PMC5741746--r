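# Survey-design data model, file IO, packaged fixture and effort summaries.

HABITAT_LEVELS <- c("amenity grassland", "dune grassland", "rough grassland", "scrub")

.required_design_cols <- c("site", "year", "habitat", "area_ha",
                           "n_visits", "acos", "transect_km")

.validate_design <- function(x) {
  missing <- setdiff(.required_design_cols, names(x))
  if (length(missing)) {
    .schema_error(paste0("survey table is missing column(s): ",
                         paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0L) .schema_error("survey table has no rows")
  num_cols <- c("year", "area_ha", "n_visits", "acos", "transect_km")
  for (cl in num_cols) {
    x[[cl]] <- suppressWarnings(as.numeric(x[[cl]]))
    if (any(is.na(x[[cl]]))) .schema_error(sprintf("column `%s` is not numeric", cl))
  }
  bad_hab <- setdiff(unique(x$habitat), HABITAT_LEVELS)
  if (length(bad_hab)) {
    .validation_error(paste0("unknown habitat label(s): ",
                             paste(bad_hab, collapse = ", ")))
  }
  if (any(x$n_visits < 1 | x$n_visits != round(x$n_visits))) {
    .validation_error("`n_visits` must be a positive integer")
  }
  if (any(x$transect_km <= 0)) .validation_error("`transect_km` must be positive")
  if (any(x$area_ha <= 0)) .validation_error("`area_ha` must be positive")
  if (any(x$acos < 0 | x$acos != round(x$acos))) {
    .validation_error("`acos` must be a nonnegative integer count")
  }
  if ("detected" %in% names(x)) {
    d <- suppressWarnings(as.numeric(x$detected))
    if (any(is.na(d)) || any(!d %in% c(0, 1))) {
      .validation_error("`detected` must be 0/1")
    }
    x$detected <- as.integer(d)
  }
  x$habitat <- factor(x$habitat, levels = HABITAT_LEVELS)
  rownames(x) <- paste0(x$site, x$year)
  class(x) <- c("survey_design", "data.frame")
  x
}

#' Read a site-year survey table
#'
#' Reads a comma-separated table with one row per site-year and the columns
#' `site`, `year`, `habitat` (one of "amenity grassland", "dune grassland",
#' "rough grassland", "scrub"), `area_ha`, `n_visits`, `acos` (artificial
#' cover objects checked per visit) and `transect_km`, plus an optional 0/1
#' `detected` flag. Rows are validated (positive lengths and areas, integer
#' visit counts, known habitat labels).
#'
#' @param path path to a CSV file.
#' @return a `survey_design` data frame, one validated row per site-year.
#' @seealso [jersey_transects()] for the packaged study fixture.
#' @export
load_survey_table <- function(path) {
  if (!file.exists(path)) .schema_error(sprintf("file not found: %s", path))
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) .schema_error(paste0("cannot parse CSV: ",
                                                         conditionMessage(e))))
  .validate_design(x)
}

#' Write a site-year survey table
#'
#' Inverse of [load_survey_table()]; `write` then `read` round-trips exactly.
#'
#' @param design a `survey_design` data frame.
#' @param path output CSV path.
#' @export
write_survey_table <- function(design, path) {
  out <- as.data.frame(design)
  out$habitat <- as.character(out$habitat)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Jersey grass snake transect fixture
#'
#' The 19 site-year transect records of the insular grass snake monitoring
#' study: habitat class, site area (ha), number of survey visits, artificial
#' cover objects (ACOs) checked per visit, and transect length (km), with a
#' site-level naive detection flag.
#'
#' Two points are package inferences rather than direct transcriptions, noted
#' here as fixture metadata: (i) the source visit column sums to 134 visits,
#' inconsistent with the study's printed totals (132 surveys, 12,335 ACO
#' checks, 613 km); setting site J's 2015 visit count to 6 reconciles all
#' three printed totals simultaneously and is the single minimal edit that
#' does so, so the fixture carries 6. (ii) per-visit detection histories were
#' not published; the site-level `detected` flags mark the 11 site-years whose
#' published empirical-Bayes abundance interval has a lower bound of at least
#' one snake (the posterior places no mass below the maximum observed count,
#' so that bound identifies the site-years with at least one detection).
#'
#' @return a `survey_design` data frame with 19 rows.
#' @export
jersey_transects <- function() {
  load_survey_table(system.file("extdata", "jersey_transects.csv",
                                package = "occumix", mustWork = TRUE))
}

#' Published transect-level estimates for the Jersey study
#'
#' Detection (p), occupancy (psi) and per-transect abundance (lambda) point
#' estimates with 95% intervals, as published for the 19 site-years. Used as
#' regression anchors: the occupancy column is reproducible from the per-km
#' occupancy 0.44 through the logit-scale log-length offset.
#'
#' @return a data frame with 19 rows keyed by `site` and `year`.
#' @export
jersey_estimates <- function() {
  x <- utils::read.csv(system.file("extdata", "jersey_estimates.csv",
                                   package = "occumix", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  rownames(x) <- paste0(x$site, x$year)
  x
}

#' Collapse a count matrix to a detection history
#'
#' Thresholds counts at one or more individuals. Missing visits (NA) stay
#' missing.
#'
#' @param counts site-year x visit matrix of nonnegative integer counts.
#' @return a 0/1 matrix of the same shape.
#' @export
build_detection_history <- function(counts) {
  counts <- .check_count_matrix(counts)
  out <- (counts >= 1) * 1
  dimnames(out) <- dimnames(counts)
  out
}

#' Read / write site-by-visit matrices
#'
#' Wide CSV layout: one row per site-year (first column `site_year`), one
#' column per visit; missing visits are empty cells.
#'
#' @param path CSV path.
#' @return `read_count_matrix`: a numeric matrix with NA for missing visits.
#' @export
read_count_matrix <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"site_year" %in% names(x)) .schema_error("matrix CSV must have a `site_year` column")
  m <- as.matrix(x[, setdiff(names(x), "site_year"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$site_year
  .check_count_matrix(m)
}

#' @rdname read_count_matrix
#' @param y matrix to write.
#' @export
write_count_matrix <- function(y, path) {
  df <- data.frame(site_year = rownames(y) %||% seq_len(nrow(y)), y,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Centre and scale continuous covariates
#'
#' Scales each requested column to sample mean 0 and SD 1, storing the
#' training mean and SD so that new design points (e.g. "a site with 10
#' ACOs") can later be projected onto the same scale. Squared terms for
#' quadratic effects should be built from the scaled column.
#'
#' @param x data frame of covariates.
#' @param cols columns to scale; defaults to all numeric columns.
#' @return `x` with the named columns replaced by their scaled versions and a
#'   `scaling` attribute (data frame of covariate, mean, sd).
#' @export
scale_covariates <- function(x, cols = NULL) {
  if (is.null(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
  sc <- data.frame(covariate = cols,
                   mean = vapply(cols, function(cl) mean(x[[cl]]), 0),
                   sd = vapply(cols, function(cl) stats::sd(x[[cl]]), 0),
                   row.names = NULL)
  if (any(sc$sd == 0)) {
    .validation_error(paste0("zero-variance covariate(s): ",
                             paste(sc$covariate[sc$sd == 0], collapse = ", ")))
  }
  for (k in seq_along(cols)) {
    x[[cols[k]]] <- (x[[cols[k]]] - sc$mean[k]) / sc$sd[k]
  }
  attr(x, "scaling") <- sc
  x
}

#' @rdname scale_covariates
#' @export
cov_scaling <- function(x) attr(x, "scaling")

#' Project raw values onto a stored covariate scale
#'
#' @param scaling a scaling table from [scale_covariates()] (or an object
#'   carrying one as attribute), or a fitted model storing one.
#' @param name covariate name.
#' @param values raw-scale values.
#' @return scaled values `(values - mean) / sd`.
#' @export
project_scaled <- function(scaling, name, values) {
  if (!is.data.frame(scaling)) scaling <- cov_scaling(scaling) %||% scaling$scaling
  i <- match(name, scaling$covariate)
  if (is.na(i)) .schema_error(sprintf("no stored scaling for covariate `%s`", name))
  (values - scaling$mean[i]) / scaling$sd[i]
}

#' Summarise survey effort
#'
#' Totals and means of the sampling effort in a survey design: total surveys,
#' ACO checks (`sum(n_visits * acos)`), kilometres walked
#' (`sum(n_visits * transect_km)`), mean ACOs per site, mean transect length,
#' and the naive occupancy (fraction of site-years with a detection). When a
#' count matrix is supplied, observation means per survey and per transect are
#' added and naive occupancy is derived from the counts.
#'
#' @param design a `survey_design` data frame.
#' @param counts optional site-year x visit count matrix aligned with `design`.
#' @return an `effort_summary` list.
#' @export
summarize_effort <- function(design, counts = NULL) {
  design <- .validate_design(as.data.frame(design))
  out <- list(
    n_site_years = nrow(design),
    total_surveys = sum(design$n_visits),
    total_aco_checks = sum(design$n_visits * design$acos),
    total_km = sum(design$n_visits * design$transect_km),
    mean_acos = mean(design$acos),
    mean_transect_km = mean(design$transect_km),
    naive_occupancy = NA_real_,
    mean_obs_per_survey = NA_real_,
    mean_obs_per_transect = NA_real_
  )
  if (!is.null(counts)) {
    counts <- .check_count_matrix(counts)
    stopifnot(nrow(counts) == nrow(design))
    out$naive_occupancy <- mean(apply(counts, 1, function(r) any(r >= 1, na.rm = TRUE)))
    out$mean_obs_per_survey <- sum(counts, na.rm = TRUE) / sum(!is.na(counts))
    out$mean_obs_per_transect <- mean(rowSums(counts, na.rm = TRUE))
  } else if ("detected" %in% names(design)) {
    out$naive_occupancy <- mean(design$detected)
  }
  structure(out, class = "effort_summary")
}

#' @export
print.effort_summary <- function(x, ...) {
  cat("Survey effort summary\n")
  cat(sprintf("  site-years: %d, surveys: %d\n", x$n_site_years, x$total_surveys))
  cat(sprintf("  ACO checks: %s, km walked: %.1f\n",
              format(x$total_aco_checks, big.mark = ","), x$total_km))
  cat(sprintf("  mean ACOs/site: %.1f, mean transect: %.2f km\n",
              x$mean_acos, x$mean_transect_km))
  if (is.finite(x$naive_occupancy))
    cat(sprintf("  naive occupancy: %.2f\n", x$naive_occupancy))
  invisible(x)
}

#' Truncate histories under a removal design
#'
#' Emulates a removal survey scheme in which a site is no longer visited after
#' its first detection: all visits after the first 1 in each row are marked
#' missing. The reduced effort totals are computed from the visits actually
#' retained; the operation never increases effort and is idempotent.
#'
#' @param history site-year x visit 0/1 matrix (NA = missing visit).
#' @param design optional `survey_design` aligned with `history`; when given,
#'   ACO-check and kilometre totals for the retained visits are reported.
#' @return list with elements `history` (truncated matrix) and `effort`
#'   (list of `total_surveys`, and `total_aco_checks`/`total_km` if `design`
#'   was supplied).
#' @export
apply_removal_design <- function(history, design = NULL) {
  history <- .check_count_matrix(history)
  if (any(history[!is.na(history)] > 1)) {
    .validation_error("`history` must be a 0/1 detection matrix")
  }
  out <- history
  for (i in seq_len(nrow(out))) {
    first <- which(out[i, ] == 1)[1]
    if (!is.na(first) && first < ncol(out)) out[i, (first + 1):ncol(out)] <- NA
  }
  kept <- rowSums(!is.na(out))
  effort <- list(total_surveys = sum(kept))
  if (!is.null(design)) {
    design <- .validate_design(as.data.frame(design))
    stopifnot(nrow(design) == nrow(out))
    effort$total_aco_checks <- sum(kept * design$acos)
    effort$total_km <- sum(kept * design$transect_km)
  }
  list(history = out, effort = effort)
}
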