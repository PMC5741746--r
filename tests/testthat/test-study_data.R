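# Data model, fixture integrity, effort summaries, removal design.

test_that("packaged fixture loads with the study's structure", {
  d <- jersey_transects()
  expect_s3_class(d, "survey_design")
  expect_identical(nrow(d), 19L)
  m14 <- d[d$site == "M" & d$year == 2014, ]
  expect_equal(m14$transect_km, 0.28)
  expect_equal(m14$acos, 6)
  expect_true(all(d$n_visits >= 1 & d$transect_km > 0 & d$area_ha > 0))
  expect_setequal(levels(d$habitat),
                  c("amenity grassland", "dune grassland",
                    "rough grassland", "scrub"))
})

test_that("survey table validation rejects malformed inputs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("", tmp)
  expect_error(load_survey_table(tmp), class = "occumix_schema_error")

  d <- as.data.frame(jersey_transects())
  d$habitat <- as.character(d$habitat)
  d2 <- d; d2$transect_km[3] <- -1
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d2, tmp2, row.names = FALSE)
  expect_error(load_survey_table(tmp2), class = "occumix_validation_error")

  d3 <- d; d3$habitat[1] <- "lawn"
  write.csv(d3, tmp2, row.names = FALSE)
  expect_error(load_survey_table(tmp2), class = "occumix_validation_error")

  d4 <- d[, setdiff(names(d), "n_visits")]
  write.csv(d4, tmp2, row.names = FALSE)
  expect_error(load_survey_table(tmp2), class = "occumix_schema_error")
})

test_that("survey tables and count matrices round-trip through CSV", {
  d <- jersey_transects()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_survey_table(d, tmp)
  d2 <- load_survey_table(tmp)
  expect_equal(as.data.frame(d2), as.data.frame(d))

  y <- simulate_counts(d, seed = 42)
  attr(y, "N") <- NULL
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_count_matrix(y, tmp2)
  expect_equal(read_count_matrix(tmp2), y)
})

test_that("counts threshold to detection histories with missingness preserved", {
  expect_equal(build_detection_history(matrix(c(0, 0, 2, 0), 2)),
               matrix(c(0, 0, 1, 0), 2))
  m <- matrix(c(NA, NA, 3, NA), 2)
  expect_equal(build_detection_history(m), matrix(c(NA, NA, 1, NA), 2))
  expect_equal(build_detection_history(matrix(12, 3, 2)), matrix(1, 3, 2))
  expect_error(build_detection_history(matrix(c(1, -1), 1)),
               class = "occumix_validation_error")
})

test_that("covariate scaling centres, stores metadata, and back-projects", {
  d <- as.data.frame(jersey_transects())
  sc <- scale_covariates(d, c("acos", "transect_km"))
  expect_equal(mean(sc$acos), 0, tolerance = 1e-10)
  expect_equal(sd(sc$acos), 1, tolerance = 1e-10)
  meta <- cov_scaling(sc)
  # study's mean effort: 95 ACOs per site (nearest integer)
  expect_equal(round(meta$mean[meta$covariate == "acos"]), 95)
  # value at the training mean scales to 0
  expect_equal(project_scaled(meta, "acos", meta$mean[meta$covariate == "acos"]), 0)
  # quadratic terms are squares of the scaled linear term
  expect_equal(sc$acos^2, ((d$acos - meta$mean[1]) / meta$sd[1])^2)
  d$flat <- 1
  expect_error(scale_covariates(d, "flat"), class = "occumix_validation_error")
})

test_that("effort totals and naive occupancy match brute-force summation", {
  d <- jersey_transects()
  s <- summarize_effort(d)
  brute_aco <- 0; brute_km <- 0
  for (i in seq_len(nrow(d))) {
    brute_aco <- brute_aco + d$n_visits[i] * d$acos[i]
    brute_km <- brute_km + d$n_visits[i] * d$transect_km[i]
  }
  expect_equal(s$total_aco_checks, brute_aco)
  expect_equal(s$total_km, brute_km)
  expect_equal(s$naive_occupancy, mean(d$detected))

  # random designs: totals equal brute force
  for (seed in 1:3) {
    g <- generate_design(25, seed = seed)
    sg <- summarize_effort(g)
    expect_equal(sg$total_aco_checks, sum(g$n_visits * g$acos))
    expect_equal(sg$total_km, sum(g$n_visits * g$transect_km))
  }

  # observation means from a count matrix
  y <- simulate_counts(d, seed = 9)
  sy <- summarize_effort(d, counts = y)
  expect_equal(sy$mean_obs_per_survey, sum(y, na.rm = TRUE) / sum(!is.na(y)))
  expect_equal(sy$naive_occupancy,
               mean(apply(y, 1, function(r) any(r >= 1, na.rm = TRUE))))
})

test_that("removal design truncates after first detection and never adds effort", {
  r <- apply_removal_design(matrix(c(0, 1, 1, 0), 1))
  expect_equal(r$history, matrix(c(0, 1, NA, NA), 1))
  allzero <- matrix(0, 2, 4)
  expect_equal(apply_removal_design(allzero)$history, allzero)

  d <- jersey_transects()
  h <- simulate_occupancy_history(d, seed = 1)
  red <- apply_removal_design(h, d)
  # independent per-row scan oracle for the reduced totals
  surv <- aco <- km <- 0
  for (i in seq_len(nrow(h))) {
    row <- h[i, !is.na(h[i, ])]
    k <- if (any(row == 1)) unname(which(row == 1)[1]) else length(row)
    surv <- surv + k; aco <- aco + k * d$acos[i]; km <- km + k * d$transect_km[i]
  }
  expect_equal(red$effort$total_surveys, surv)
  expect_equal(red$effort$total_aco_checks, aco)
  expect_equal(red$effort$total_km, km)

  full <- summarize_effort(d)
  expect_lte(red$effort$total_surveys, full$total_surveys)
  expect_lte(red$effort$total_aco_checks, full$total_aco_checks)
  # idempotence
  again <- apply_removal_design(red$history, d)
  expect_equal(again$history, red$history)
  expect_equal(again$effort, red$effort)
})
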