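#' Parameters of a synthetic patient cohort
#'
#' The generator emulates the structure of a 44-patient individual-level
#' validation study: each patient carries a latent health-status severity
#' theta on the 0--6 CCQ scale, plus the usual cohort characteristics (age,
#' FEV1 % predicted, GOLD stage, sex, current exacerbation).  Defaults match
#' the published cohort marginals: severity 2.2 (SD 0.9), age 66.1 (7.4),
#' FEV1 %pred 44.8 (13.8), GOLD II/III/IV in proportions 13/26/5, 32/44
#' male, 5/44 in exacerbation.
#'
#' In Likert mode the severity is clipped to \[0, 6\] and item answers are
#' rounded to the 0..6 grid; `continuous = TRUE` skips both the rounding and
#' the clipping, so that all scores stay exactly Gaussian and the population
#' agreement of [population_agreement()] is exact (used for estimator
#' validation, where boundary effects would blur the known truth).
#'
#' @param n_patients cohort size (default 44).
#' @param severity_mean,severity_sd latent severity distribution on the CCQ
#'   scale.
#' @param item_noise_sd named vector of item-level noise SDs per domain
#'   (`symptoms`, `mental`, `functional`): the scatter of a respondent's
#'   individual item answers around the perceived severity.
#' @param age_mean,age_sd,fev1_mean,fev1_sd cohort characteristic marginals.
#' @param gold_probs probabilities of GOLD stages II/III/IV (normalized).
#' @param p_male,p_exacerbation binary covariate probabilities.
#' @param continuous skip Likert discretization and clipping.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 44,
                          severity_mean = 2.2, severity_sd = 0.9,
                          item_noise_sd = c(symptoms = 0.8, mental = 1.0,
                                            functional = 0.9),
                          age_mean = 66.1, age_sd = 7.4,
                          fev1_mean = 44.8, fev1_sd = 13.8,
                          gold_probs = c(II = 13, III = 26, IV = 5) / 44,
                          p_male = 32 / 44, p_exacerbation = 5 / 44,
                          continuous = FALSE) {
  if (n_patients < 1) ccq_validation_error("n_patients must be positive")
  if (severity_sd < 0 || age_sd <= 0 || fev1_sd <= 0) {
    ccq_validation_error("SD parameters must be positive")
  }
  if (!all(c("symptoms", "mental", "functional") %in% names(item_noise_sd)) ||
      any(item_noise_sd < 0)) {
    ccq_validation_error(
      "item_noise_sd must be a nonnegative vector named symptoms/mental/functional")
  }
  if (any(gold_probs < 0) || sum(gold_probs) <= 0) {
    ccq_validation_error("gold_probs must be nonnegative with positive sum")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      severity_mean = severity_mean, severity_sd = severity_sd,
      item_noise_sd = item_noise_sd[c("symptoms", "mental", "functional")],
      age_mean = age_mean, age_sd = age_sd,
      fev1_mean = fev1_mean, fev1_sd = fev1_sd,
      gold_probs = gold_probs / sum(gold_probs),
      p_male = p_male, p_exacerbation = p_exacerbation,
      continuous = isTRUE(continuous)
    ),
    class = "cohort_params"
  )
}

#' Parameters of the simulated raters
#'
#' Every rater perceives a patient's latent severity theta through a linear
#' filter with role-specific location bias `a`, scale `b` and Gaussian
#' perception noise: perceived = `a + b*theta + N(0, sd^2)`.  The patient
#' also rates through noise (`patient_sd`) but without bias.  Reviewer
#' heterogeneity is modelled by drawing each reviewer's own location bias
#' once per study from `N(reviewer_a_mean, reviewer_a_sd^2)`, so the "mean
#' of five reviewers" genuinely averages heterogeneous raters.
#'
#' Defaults are calibration choices (no published rater-error magnitudes
#' exist) set so that the population patient-vs-treating CCC is about 0.87
#' and patient-vs-reviewer-mean about 0.86 on the continuous scale.
#'
#' @param patient_sd perception noise SD of the patient's own rating.
#' @param treating_a,treating_b,treating_sd treating clinician's bias,
#'   scale and perception noise SD.
#' @param reviewer_a_mean,reviewer_a_sd hyper-distribution of per-reviewer
#'   location biases.
#' @param reviewer_b,reviewer_sd reviewers' common scale and perception
#'   noise SD.
#' @return An object of class `rater_params`.
#' @export
rater_params <- function(patient_sd = 0.2,
                         treating_a = 0, treating_b = 1, treating_sd = 0.2,
                         reviewer_a_mean = 0, reviewer_a_sd = 0.5,
                         reviewer_b = 1, reviewer_sd = 0.63) {
  if (treating_b <= 0 || reviewer_b <= 0) {
    ccq_validation_error("rater scale parameters b must be positive")
  }
  if (min(patient_sd, treating_sd, reviewer_a_sd, reviewer_sd) < 0) {
    ccq_validation_error("rater noise SDs must be nonnegative")
  }
  structure(
    list(patient_sd = patient_sd,
         treating_a = treating_a, treating_b = treating_b,
         treating_sd = treating_sd,
         reviewer_a_mean = reviewer_a_mean, reviewer_a_sd = reviewer_a_sd,
         reviewer_b = reviewer_b, reviewer_sd = reviewer_sd),
    class = "rater_params"
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` latent severities and characteristics per
#' [cohort_params()].  Deterministic given the seed.
#'
#' @param params a [cohort_params()].
#' @param seed integer seed.
#' @return Data frame: `subject_id` (`"P001"`, ...), `theta` (latent
#'   severity), `age`, `fev1_pct`, `gold`, `sex`, `exacerbation`.
#' @export
generate_cohort <- function(params = cohort_params(), seed) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  with_seed(seed, {
    theta <- rnorm(n, params$severity_mean, params$severity_sd)
    if (!params$continuous) theta <- pmin(pmax(theta, 0), 6)
    data.frame(
      # zero-padded so lexicographic subject order equals cohort order
      subject_id = sprintf("P%0*d", max(3L, nchar(n)), seq_len(n)),
      theta = theta,
      age = rnorm(n, params$age_mean, params$age_sd),
      fev1_pct = rnorm(n, params$fev1_mean, params$fev1_sd),
      gold = sample(names(params$gold_probs), n, replace = TRUE,
                    prob = params$gold_probs),
      sex = ifelse(rbinom(n, 1, params$p_male) == 1, "male", "female"),
      exacerbation = rbinom(n, 1, params$p_exacerbation) == 1,
      stringsAsFactors = FALSE
    )
  })
}

# item answers for a block of forms: row f gets its perceived severity plus
# per-item domain noise, discretized to the 0..6 grid unless continuous
draw_item_matrix <- function(perceived, map, item_noise_sd, continuous) {
  nf <- length(perceived)
  items <- matrix(0, nrow = nf, ncol = 10)
  for (dom in names(map)) {
    idx <- map[[dom]]
    items[, idx] <- perceived +
      matrix(rnorm(nf * length(idx), 0, item_noise_sd[[dom]]),
             nrow = nf)
  }
  if (!continuous) items <- pmin(pmax(round(items), 0), 6)
  colnames(items) <- item_cols
  items
}

#' Generate the ratings of a synthetic study
#'
#' Produces, per subject: one patient form (items drawn around the
#' patient's own noisy perception of theta), one treating-clinician form
#' (around `a + b*theta` plus noise), and the design-assigned reviewer
#' forms (around each reviewer's own bias plus common scale).  Items are
#' rounded and clipped to 0..6 unless the cohort is continuous.
#'
#' @param cohort a [generate_cohort()] result.
#' @param rater a [rater_params()].
#' @param design a [build_review_design()] with `n_patients` rows.
#' @param seed integer seed.
#' @param params the [cohort_params()] used for the cohort (supplies the
#'   item noise SDs and the continuous flag).
#' @param map a [ccq_domain_map()].
#' @return An object of class `generated_study`: `ratings` (long-format
#'   data frame in the exact CSV schema), `dataset` (a reconciled
#'   `study_dataset`), `truth` (subject id + theta), `reviewer_biases`,
#'   `params`, `rater`, `seed`.
#' @export
generate_ratings <- function(cohort, rater = rater_params(), design,
                             seed, params = cohort_params(),
                             map = ccq_domain_map()) {
  stopifnot(inherits(rater, "rater_params"),
            inherits(design, "review_assignment"),
            inherits(params, "cohort_params"))
  n <- nrow(cohort)
  if (n != design$n_patients) {
    ccq_validation_error(sprintf(
      "design is for %d patients but the cohort has %d",
      design$n_patients, n))
  }
  cont <- params$continuous
  noise_sd <- params$item_noise_sd

  with_seed(seed, {
    reviewer_biases <- rnorm(design$n_reviewers, rater$reviewer_a_mean,
                             rater$reviewer_a_sd)
    th <- cohort$theta

    block <- function(subject_id, role, rater_id, perceived) {
      cbind(
        data.frame(subject_id = subject_id, rater_role = role,
                   rater_id = rater_id, stringsAsFactors = FALSE),
        as.data.frame(draw_item_matrix(perceived, map, noise_sd, cont))
      )
    }
    patient_block <- block(
      cohort$subject_id, "patient", NA_character_,
      th + rnorm(n, 0, rater$patient_sd))
    treating_block <- block(
      cohort$subject_id, "treating", NA_character_,
      rater$treating_a + rater$treating_b * th +
        rnorm(n, 0, rater$treating_sd))
    pat <- design$assignments$patient
    rev <- design$assignments$reviewer
    reviewer_block <- block(
      cohort$subject_id[pat], "reviewer", as.character(rev),
      reviewer_biases[rev] + rater$reviewer_b * th[pat] +
        rnorm(length(pat), 0, rater$reviewer_sd))
    ratings <- rbind(patient_block, treating_block, reviewer_block)

    cfg <- ccq_config(domain_map = map, likert = !cont)
    scores <- score_forms(ratings, map = map, likert = !cont)
    dataset <- build_study_dataset(scores, design, cfg)

    structure(
      list(
        ratings = ratings,
        dataset = dataset,
        truth = cohort[c("subject_id", "theta")],
        reviewer_biases = reviewer_biases,
        params = params, rater = rater, design = design,
        seed = as.integer(seed)
      ),
      class = "generated_study"
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: builds the balanced review design, draws the
#' cohort and all ratings, and optionally writes the ratings CSV, design
#' CSV and ground-truth JSON in the exact formats [load_study()] consumes.
#'
#' @param params a [cohort_params()].
#' @param rater a [rater_params()].
#' @param n_reviewers,reviews_per_patient design counts (defaults 20 and 5,
#'   the study instance).
#' @param seed integer seed governing design, cohort and ratings.
#' @param out_dir if non-`NULL`, write `ratings.csv`, `design.csv`,
#'   `truth.json` there.
#' @return A `generated_study` (see [generate_ratings()]).
#' @examples
#' study <- simulate_study(seed = 1)
#' run_study(study$dataset)
#' @export
simulate_study <- function(params = cohort_params(), rater = rater_params(),
                           n_reviewers = 20, reviews_per_patient = 5,
                           seed, out_dir = NULL) {
  design <- build_review_design(params$n_patients, n_reviewers,
                                reviews_per_patient, seed = seed)
  cohort <- generate_cohort(params, seed = seed + 1)
  study <- generate_ratings(cohort, rater, design, seed = seed + 2,
                            params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratings(study$ratings, file.path(out_dir, "ratings.csv"))
    write_design(design, file.path(out_dir, "design.csv"))
    jsonlite::write_json(
      list(truth = study$truth, reviewer_biases = study$reviewer_biases,
           seed = study$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  study
}

#' Population agreement of the generative model
#'
#' Closed-form population values of the agreement suite implied by the
#' generator on the continuous scale, where the paired total scores are
#' exactly bivariate normal: the patient total is
#' `X = theta + e_x` and a rater total is `Y = a + b*theta + e_y`, with
#' `cov(X, Y) = b*var(theta)` and the error variances collecting perception
#' noise plus the item-average noise `sum(n_dom * sd_dom^2)/100` (and, for
#' the reviewer mean of `k` reviewers, the between-reviewer bias variance
#' `reviewer_a_sd^2/k` plus the within-reviewer variance divided by `k`).
#' The closed forms anchor the estimators to known truth in validation
#' runs.
#'
#' @param params a [cohort_params()] (continuous-mode semantics).
#' @param rater a [rater_params()].
#' @param comparison which pair of score series.
#' @param p TDI proportion; `delta` CP half-width.
#' @param delta see above.
#' @param reviews_per_patient number of reviewers averaged per patient.
#' @return List with `ccc`, `precision`, `accuracy`, `cp`, `tdi`, `icc`
#'   (equal to `ccc` at the population level) and the population moments
#'   (`mu_x`, `mu_y`, `var_x`, `var_y`, `cov_xy`, `mu_d`, `sigma_d2`,
#'   `msd`).
#' @export
population_agreement <- function(params = cohort_params(),
                                 rater = rater_params(),
                                 comparison = c("patient_treating",
                                                "patient_reviewer_mean",
                                                "treating_reviewer_mean"),
                                 p = 0.9, delta = 0.4,
                                 reviews_per_patient = 5) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(params, "cohort_params"), inherits(rater, "rater_params"))
  k <- reviews_per_patient
  var_th <- params$severity_sd^2
  mu_th <- params$severity_mean
  item_var <- sum(c(4, 2, 4) * params$item_noise_sd[
    c("symptoms", "mental", "functional")]^2) / 100

  side <- function(role) {
    switch(role,
      patient = list(a = 0, b = 1,
                     err = rater$patient_sd^2 + item_var),
      treating = list(a = rater$treating_a, b = rater$treating_b,
                      err = rater$treating_sd^2 + item_var),
      reviewer_mean = list(
        a = rater$reviewer_a_mean, b = rater$reviewer_b,
        err = rater$reviewer_a_sd^2 / k +
          (rater$reviewer_sd^2 + item_var) / k)
    )
  }
  roles <- switch(comparison,
    patient_treating = c("patient", "treating"),
    patient_reviewer_mean = c("patient", "reviewer_mean"),
    treating_reviewer_mean = c("treating", "reviewer_mean"))
  sx <- side(roles[1]); sy <- side(roles[2])

  mu_x <- sx$a + sx$b * mu_th
  mu_y <- sy$a + sy$b * mu_th
  var_x <- sx$b^2 * var_th + sx$err
  var_y <- sy$b^2 * var_th + sy$err
  cov_xy <- sx$b * sy$b * var_th
  agreement_from_population_moments(mu_x, mu_y, var_x, var_y, cov_xy,
                                    p = p, delta = delta)
}

# Same formulas as the sample estimators, applied to population moments.
agreement_from_population_moments <- function(mu_x, mu_y, var_x, var_y,
                                              cov_xy, p = 0.9, delta = 0.4) {
  mu_d <- mu_x - mu_y
  sigma_d2 <- var_x + var_y - 2 * cov_xy
  msd <- mu_d^2 + sigma_d2
  ccc <- 2 * cov_xy / (var_x + var_y + mu_d^2)
  rho <- cov_xy / sqrt(var_x * var_y)
  v <- sqrt(var_x / var_y)
  u <- mu_d / sqrt(sqrt(var_x) * sqrt(var_y))
  list(
    ccc = ccc,
    precision = rho,
    accuracy = if (rho == 0) 2 / (v + 1 / v + u^2) else ccc / rho,
    cp = cp_from_moments(mu_d, sigma_d2, delta),
    tdi = tdi_from_moments(mu_d, msd, p, mode = "exact"),
    icc = ccc,
    mu_x = mu_x, mu_y = mu_y, var_x = var_x, var_y = var_y,
    cov_xy = cov_xy, mu_d = mu_d, sigma_d2 = sigma_d2, msd = msd,
    p = p, delta = delta
  )
}
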