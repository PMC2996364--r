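# Synthetic study generator: cohort marginals, rater model, population
# closed forms, parameter recovery.

test_that("cohort moments converge to the configured marginals", {
  cohort <- generate_cohort(cohort_params(n_patients = 10000), seed = 51)
  # severity 2.2 (0.9) with clipping-adjusted tolerance
  expect_lt(abs(mean(cohort$theta) - 2.2), 0.05)
  expect_lt(abs(sd(cohort$theta) - 0.9), 0.05)
  expect_lt(abs(mean(cohort$age) - 66.1), 0.3)
  expect_lt(abs(mean(cohort$fev1_pct) - 44.8), 0.5)
  expect_lt(abs(mean(cohort$gold == "III") - 26 / 44), 0.02)
  expect_lt(abs(mean(cohort$sex == "male") - 32 / 44), 0.02)
  expect_true(all(cohort$theta >= 0 & cohort$theta <= 6))
})

test_that("degenerate and deterministic generation behave as constructed", {
  p0 <- cohort_params(n_patients = 20, severity_sd = 0)
  c0 <- generate_cohort(p0, seed = 52)
  expect_equal(c0$theta, rep(2.2, 20))

  c1 <- generate_cohort(cohort_params(), seed = 53)
  c2 <- generate_cohort(cohort_params(), seed = 53)
  expect_identical(c1, c2)

  s1 <- simulate_study(seed = 54)
  s2 <- simulate_study(seed = 54)
  expect_identical(s1$ratings, s2$ratings)
  expect_identical(s1$reviewer_biases, s2$reviewer_biases)

  expect_error(cohort_params(severity_sd = -1),
               class = "ccq_validation_error")
  expect_error(rater_params(treating_b = 0),
               class = "ccq_validation_error")
})

test_that("zero-noise continuous generation reproduces the patient exactly", {
  params <- cohort_params(
    n_patients = 16, continuous = TRUE,
    item_noise_sd = c(symptoms = 0, mental = 0, functional = 0))
  rater <- rater_params(patient_sd = 0, treating_a = 0, treating_b = 1,
                        treating_sd = 0, reviewer_a_mean = 0,
                        reviewer_a_sd = 0, reviewer_sd = 0)
  study <- simulate_study(params, rater, n_reviewers = 4,
                          reviews_per_patient = 2, seed = 55)
  ds <- study$dataset
  expect_equal(ds$treating$total, ds$patient$total, tolerance = 1e-12)
  expect_equal(ds$reviewer_means$total, ds$patient$total,
               tolerance = 1e-12)
  expect_equal(ds$patient$total, study$truth$theta, tolerance = 1e-12)
  expect_equal(ccc(ds$patient$total, ds$treating$total)$estimate, 1)

  # a pure bias a = 0.5 appears as Bland-Altman bias -0.5 exactly
  rater_b <- rater_params(patient_sd = 0, treating_a = 0.5, treating_b = 1,
                          treating_sd = 0, reviewer_a_sd = 0,
                          reviewer_sd = 0)
  study_b <- simulate_study(params, rater_b, n_reviewers = 4,
                            reviews_per_patient = 2, seed = 56)
  ba <- bland_altman(study_b$dataset$patient$total,
                     study_b$dataset$treating$total)
  expect_equal(ba$bias, -0.5, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0, tolerance = 1e-12)
})

test_that("population closed forms match their constructions", {
  no_item <- c(symptoms = 0, mental = 0, functional = 0)
  perfect <- population_agreement(
    cohort_params(continuous = TRUE, item_noise_sd = no_item),
    rater_params(patient_sd = 0, treating_a = 0, treating_b = 1,
                 treating_sd = 0))
  expect_equal(perfect$ccc, 1)
  expect_equal(perfect$cp, 1)
  expect_equal(perfect$tdi, 0)

  # sd_theta 1, both error SDs 0.5: precision 1/1.25 = 0.8, accuracy 1
  pop <- population_agreement(
    cohort_params(continuous = TRUE, severity_sd = 1, item_noise_sd = no_item),
    rater_params(patient_sd = 0.5, treating_a = 0, treating_b = 1,
                 treating_sd = 0.5))
  expect_equal(pop$precision, 0.8)
  expect_equal(pop$accuracy, 1)
  expect_equal(pop$ccc, 0.8)

  # mu_d 0, sigma_d 0.4 at delta 0.4: CP = Phi(1) - Phi(-1)
  s <- sqrt(0.08)
  pop2 <- population_agreement(
    cohort_params(continuous = TRUE, item_noise_sd = no_item),
    rater_params(patient_sd = s, treating_a = 0, treating_b = 1,
                 treating_sd = s),
    delta = 0.4)
  expect_equal(pop2$cp, pnorm(1) - pnorm(-1), tolerance = 1e-12)
})

test_that("empirical generator moments converge to the closed forms", {
  # homogeneous reviewers here: with a handful of reviewers the
  # once-per-study bias draws keep their sample variance far from the
  # hyper-variance, so the bias-heterogeneity term is checked separately
  params <- cohort_params(n_patients = 100000, continuous = TRUE)
  rater <- rater_params(reviewer_a_sd = 0)
  study <- simulate_study(params, rater, n_reviewers = 4,
                          reviews_per_patient = 1, seed = 57)
  pop <- population_agreement(params, rater, "patient_treating")
  x <- study$dataset$patient$total
  y <- study$dataset$treating$total
  ms <- moment_summary(x, y)
  expect_equal(ms$x_bar, pop$mu_x, tolerance = 0.01)
  expect_equal(ms$y_bar, pop$mu_y, tolerance = 0.01)
  expect_equal(ms$sx2, pop$var_x, tolerance = 0.01)
  expect_equal(ms$sy2, pop$var_y, tolerance = 0.01)
  expect_equal(ms$sxy, pop$cov_xy, tolerance = 0.01)

  # reviewer-mean closed form with k = 1: full per-reviewer variance
  pop_rm <- population_agreement(params, rater, "patient_reviewer_mean",
                                 reviews_per_patient = 1)
  ym <- study$dataset$reviewer_means$total
  expect_equal(var(ym), pop_rm$var_y, tolerance = 0.02)

  # bias heterogeneity: averaging k heterogeneous reviewers leaves
  # reviewer_a_sd^2/k in the reviewer-mean variance
  het <- rater_params(reviewer_a_sd = 0.5)
  v5 <- population_agreement(params, het, "patient_reviewer_mean",
                             reviews_per_patient = 5)$var_y
  v1 <- population_agreement(params, het, "patient_reviewer_mean",
                             reviews_per_patient = 1)$var_y
  v5_h <- population_agreement(params, rater, "patient_reviewer_mean",
                               reviews_per_patient = 5)$var_y
  expect_equal(v5 - v5_h, 0.5^2 / 5)
  expect_gt(v1, v5)
})

test_that("Likert discretization attenuates rather than inflates concordance", {
  base <- list(n_patients = 2000,
               item_noise_sd = c(symptoms = 0.8, mental = 1.0,
                                 functional = 0.9))
  cont <- do.call(cohort_params, c(base, list(continuous = TRUE)))
  disc <- do.call(cohort_params, c(base, list(continuous = FALSE)))
  get_ccc <- function(params, seed) {
    study <- simulate_study(params, seed = seed, n_reviewers = 4,
                            reviews_per_patient = 1)
    ds <- study$dataset
    ccc(ds$patient$total, ds$treating$total)$estimate
  }
  # documented property: rounding plus clipping should not raise the CCC
  # beyond sampling noise
  expect_lt(get_ccc(disc, 58), get_ccc(cont, 58) + 0.02)
})

test_that("sample CCC recovers the constructed population value", {
  # population CCC 0.85 by construction: sd_theta 0.9, equal error SDs
  s <- sqrt(0.81 * (1 / 0.85 - 1))
  params <- cohort_params(
    n_patients = 2000, continuous = TRUE,
    item_noise_sd = c(symptoms = 0, mental = 0, functional = 0))
  rater <- rater_params(patient_sd = s, treating_a = 0, treating_b = 1,
                        treating_sd = s, reviewer_a_sd = 0, reviewer_sd = 1)
  pop <- population_agreement(params, rater, "patient_treating")
  expect_equal(pop$ccc, 0.85, tolerance = 1e-12)

  ests <- vapply(1:20, function(seed) {
    study <- simulate_study(params, rater, n_reviewers = 4,
                            reviews_per_patient = 1, seed = 1000 + seed)
    ds <- study$dataset
    ccc(ds$patient$total, ds$treating$total)$estimate
  }, numeric(1))
  expect_gte(mean(abs(ests - 0.85) <= 0.02), 0.95)
  expect_lt(abs(mean(ests) - 0.85), 0.01)
})
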