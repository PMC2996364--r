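#' Build a balanced randomized reviewer assignment
#'
#' Assigns each patient's interview to `reviews_per_patient` distinct
#' reviewers from a pool of `n_reviewers` so that every reviewer receives
#' exactly `n_patients * reviews_per_patient / n_reviewers` interviews (the
#' study instance: 44 patients, 20 reviewers, 5 reviews per patient, hence 11
#' interviews per reviewer set).  The order of the interviews inside each
#' reviewer's set is randomized.
#'
#' Construction: a cyclic balanced template (patient `i` is assigned the
#' consecutive reviewer residues `i*k .. i*k + k - 1` modulo `R`, which is
#' exactly balanced whenever `R` divides `P*k`) is randomized by uniform
#' random relabeling of patients and of reviewers.  Relabeling preserves the
#' balance exactly and, by permutation symmetry, gives every
#' (patient, reviewer) pair the exact marginal assignment probability `k/R`.
#'
#' @param n_patients number of patients (interviews), `P`.
#' @param n_reviewers size of the reviewer pool, `R`.
#' @param reviews_per_patient reviewers per patient, `k` (must satisfy
#'   `k <= R` and `R | P*k`).
#' @param seed integer seed; identical seeds reproduce identical designs.
#' @return An object of class `review_assignment`: list with counts,
#'   `incidence` (P x R 0/1 matrix), `assignments` (data frame `patient`,
#'   `reviewer`, `position_in_set`), `per_reviewer_order` (list of patient
#'   vectors in presentation order), and `seed`.
#' @examples
#' d <- build_review_design(44, 20, 5, seed = 1)
#' all(colSums(d$incidence) == 11)
#' @export
build_review_design <- function(n_patients, n_reviewers, reviews_per_patient,
                                seed) {
  P <- as.integer(n_patients)
  R <- as.integer(n_reviewers)
  k <- as.integer(reviews_per_patient)
  if (any(is.na(c(P, R, k))) || P < 1L || R < 1L || k < 1L) {
    ccq_infeasibility_error("counts must be positive integers")
  }
  if (k > R) {
    ccq_infeasibility_error(sprintf(
      "infeasible design: reviews_per_patient (%d) exceeds n_reviewers (%d)",
      k, R))
  }
  if ((P * k) %% R != 0L) {
    ccq_infeasibility_error(sprintf(
      "infeasible design: n_patients * reviews_per_patient = %d is not divisible by n_reviewers = %d",
      P * k, R))
  }
  per_reviewer <- (P * k) %/% R

  with_seed(seed, {
    perm_p <- sample.int(P)   # template row for each patient label
    perm_r <- sample.int(R)   # reviewer label for each template column
    incidence <- matrix(0L, nrow = P, ncol = R,
                        dimnames = list(patient = NULL, reviewer = NULL))
    for (i in seq_len(P)) {
      template_row <- perm_p[i] - 1L
      cols <- (template_row * k + seq_len(k) - 1L) %% R + 1L
      incidence[i, perm_r[cols]] <- 1L
    }
    per_reviewer_order <- lapply(seq_len(R), function(r) {
      pts <- which(incidence[, r] == 1L)
      pts[sample.int(length(pts))]
    })
    assignments <- do.call(rbind, lapply(seq_len(R), function(r) {
      data.frame(patient = per_reviewer_order[[r]],
                 reviewer = r,
                 position_in_set = seq_along(per_reviewer_order[[r]]))
    }))
    structure(
      list(
        n_patients = P, n_reviewers = R, reviews_per_patient = k,
        reviews_per_reviewer = per_reviewer,
        incidence = incidence,
        assignments = assignments,
        per_reviewer_order = per_reviewer_order,
        seed = as.integer(seed)
      ),
      class = "review_assignment"
    )
  })
}

#' @export
print.review_assignment <- function(x, ...) {
  cat(sprintf(
    "Balanced review design: %d patients x %d reviewers, %d reviews/patient (%d interviews per reviewer set), seed %d\n",
    x$n_patients, x$n_reviewers, x$reviews_per_patient,
    x$reviews_per_reviewer, x$seed))
  invisible(x)
}

# Internal sanity check used by tests and the pipeline.
check_review_assignment <- function(design) {
  inc <- design$incidence
  problems <- character(0)
  if (!all(rowSums(inc) == design$reviews_per_patient)) {
    problems <- c(problems, "some patient is not reviewed exactly k times")
  }
  if (!all(colSums(inc) == design$reviews_per_reviewer)) {
    problems <- c(problems, "reviewer set sizes are unbalanced")
  }
  if (!all(inc %in% c(0L, 1L))) {
    problems <- c(problems, "a patient is assigned twice to the same reviewer")
  }
  problems
}

#' Write / read a review design as CSV
#'
#' Columns: `patient_id`, `reviewer_id`, `position_in_set` (the interview's
#' position inside the reviewer's randomized packet).
#'
#' @param design a [build_review_design()] result.
#' @param path CSV file path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(
    patient_id = design$assignments$patient,
    reviewer_id = design$assignments$reviewer,
    position_in_set = design$assignments$position_in_set
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @return `read_design()`: a `review_assignment` reconstructed from the CSV
#'   (seed unknown, recorded as `NA`).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    ccq_validation_error(sprintf("design file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "reviewer_id", "position_in_set")
  if (!all(required %in% names(df))) {
    ccq_validation_error(paste0(
      "malformed design CSV, expected columns: ",
      paste(required, collapse = ", ")))
  }
  P <- max(df$patient_id)
  R <- max(df$reviewer_id)
  incidence <- matrix(0L, nrow = P, ncol = R)
  incidence[cbind(df$patient_id, df$reviewer_id)] <- 1L
  k <- unique(rowSums(incidence))
  per_reviewer <- unique(colSums(incidence))
  if (length(k) != 1L || length(per_reviewer) != 1L) {
    ccq_validation_error("design CSV does not describe a balanced assignment")
  }
  per_reviewer_order <- lapply(seq_len(R), function(r) {
    sub <- df[df$reviewer_id == r, ]
    sub$patient_id[order(sub$position_in_set)]
  })
  structure(
    list(
      n_patients = P, n_reviewers = R, reviews_per_patient = as.integer(k),
      reviews_per_reviewer = as.integer(per_reviewer),
      incidence = incidence,
      assignments = data.frame(patient = df$patient_id,
                               reviewer = df$reviewer_id,
                               position_in_set = df$position_in_set),
      per_reviewer_order = per_reviewer_order,
      seed = NA_integer_
    ),
    class = "review_assignment"
  )
}

#' Average reviewer scores per patient
#'
#' Computes, for each patient, the arithmetic mean of the assigned reviewers'
#' total and domain scores (the study aggregates "the mean of the scores of
#' the five reviewing clinicians").  The supplied scores must reconcile
#' exactly with the design: one score per assigned (patient, reviewer) pair,
#' none missing, none extra.
#'
#' @param scores data frame with columns `patient`, `reviewer`, `total`,
#'   `symptoms`, `mental`, `functional` (integer patient/reviewer indices
#'   matching the design).
#' @param design a [build_review_design()] result.
#' @return Data frame with one row per patient: `patient`, `total`,
#'   `symptoms`, `mental`, `functional` (reviewer means).
#' @export
aggregate_reviewers <- function(scores, design) {
  required <- c("patient", "reviewer", "total", "symptoms", "mental",
                "functional")
  if (!all(required %in% names(scores))) {
    ccq_validation_error(paste0(
      "reviewer score table must have columns: ",
      paste(required, collapse = ", ")))
  }
  assigned <- paste(design$assignments$patient, design$assignments$reviewer,
                    sep = ":")
  got <- paste(scores$patient, scores$reviewer, sep = ":")
  missing <- setdiff(assigned, got)
  extra <- setdiff(got, assigned)
  dup <- got[duplicated(got)]
  if (length(missing) || length(extra) || length(dup)) {
    parts <- character(0)
    if (length(missing)) parts <- c(parts, paste0(
      "missing scores for (patient:reviewer) ",
      paste(head(missing, 10), collapse = ", ")))
    if (length(extra)) parts <- c(parts, paste0(
      "scores for unassigned (patient:reviewer) ",
      paste(head(extra, 10), collapse = ", ")))
    if (length(dup)) parts <- c(parts, paste0(
      "duplicated scores for (patient:reviewer) ",
      paste(head(unique(dup), 10), collapse = ", ")))
    ccq_reconciliation_error(paste(parts, collapse = "; "))
  }
  out <- aggregate(scores[c("total", "symptoms", "mental", "functional")],
                   by = list(patient = scores$patient), FUN = mean)
  out[order(out$patient), , drop = FALSE]
}
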