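# Shared fixtures, built in code.

# a random valid Likert form
random_form <- function(subject_id = "p1", role = "patient") {
  ccq_form(subject_id, role, sample(0:6, 10, replace = TRUE),
           rater_id = if (role == "reviewer") "r1" else NA)
}

# paired bivariate-normal scores with a shared latent component:
# x = theta + e1, y = a + b*theta + e2
paired_normal <- function(n, a = 0, b = 1, sd_theta = 1,
                          sd_x = 0.5, sd_y = 0.5, mu_theta = 2.2) {
  theta <- rnorm(n, mu_theta, sd_theta)
  list(x = theta + rnorm(n, 0, sd_x),
       y = a + b * theta + rnorm(n, 0, sd_y))
}

# x, y with exactly specified differences (x - y = d)
pairs_with_diffs <- function(d, x = seq_along(d)) {
  list(x = x, y = x - d)
}

# a vector with mean 0 and 1/n-denominator SD exactly `s`
exact_sd_vector <- function(n, s) {
  v <- rnorm(n)
  v <- v - mean(v)
  v / sqrt(mean(v^2)) * s
}

# tiny all-roles study where every rater copies the patient's form
perfect_copy_study <- function(n_patients = 12, n_reviewers = 4,
                               reviews_per_patient = 2, seed = 42) {
  design <- build_review_design(n_patients, n_reviewers,
                                reviews_per_patient, seed = seed)
  items <- withr_seed_items(n_patients, seed)
  subject_id <- sprintf("P%03d", seq_len(n_patients))
  base <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  mk <- function(role, rater_id) {
    out <- cbind(base, rater_role = role, rater_id = rater_id, items)
    out
  }
  ratings <- rbind(
    mk("patient", NA_character_),
    mk("treating", NA_character_),
    do.call(rbind, lapply(seq_len(nrow(design$assignments)), function(j) {
      p <- design$assignments$patient[j]
      r <- design$assignments$reviewer[j]
      cbind(base[p, , drop = FALSE], rater_role = "reviewer",
            rater_id = as.character(r), items[p, , drop = FALSE])
    }))
  )
  scores <- score_forms(ratings)
  list(ratings = ratings, design = design,
       dataset = ccqagree:::build_study_dataset(scores, design, ccq_config()))
}

withr_seed_items <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- matrix(sample(0:6, n * 10, replace = TRUE), nrow = n)
  colnames(m) <- paste0("item_", 1:10)
  as.data.frame(m)
}
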