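#' Analysis configuration
#'
#' Collects the tunable choices of the pipeline in one validated object:
#' the item-to-domain map, the MCID half-width used for the Coverage
#' Probability and the Bland-Altman band, the TDI proportion, the moment
#' denominator convention, the confidence-limit sidedness, the missing-item
#' policy, and whether scores are on the continuous (non-Likert) scale.
#'
#' @param domain_map a [ccq_domain_map()].
#' @param delta MCID half-width on the score scale (default 0.4).
#' @param p TDI proportion (default 0.9).
#' @param denominator `"n"` or `"n_minus_1"` moment convention.
#' @param ci `"one-sided"` or `"two-sided"` confidence limits.
#' @param missing_policy `"strict"` or `"prorate"` (see [score_ccq()]).
#' @param likert whether item answers must be 0..6 integers.
#' @param tdi_mode `"approx"` or `"exact"` (see [tdi()]).
#' @param domain_tables also emit domain-level agreement tables (default
#'   `FALSE`; the standard report carries domain-level Bland-Altman data
#'   only).
#' @return An object of class `ccq_config`.
#' @export
ccq_config <- function(domain_map = ccq_domain_map(), delta = 0.4, p = 0.9,
                       denominator = c("n", "n_minus_1"),
                       ci = c("one-sided", "two-sided"),
                       missing_policy = c("strict", "prorate"),
                       likert = TRUE,
                       tdi_mode = c("approx", "exact"),
                       domain_tables = FALSE) {
  stopifnot(inherits(domain_map, "ccq_domain_map"))
  if (!is.numeric(delta) || delta <= 0) {
    ccq_validation_error("config: delta must be positive")
  }
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    ccq_validation_error("config: p must lie strictly between 0 and 1")
  }
  structure(
    list(
      domain_map = domain_map, delta = delta, p = p,
      denominator = match.arg(denominator),
      ci = match.arg(ci),
      missing_policy = match.arg(missing_policy),
      likert = isTRUE(likert),
      tdi_mode = match.arg(tdi_mode),
      domain_tables = isTRUE(domain_tables),
      icc_variant = "ICC(A,1)"
    ),
    class = "ccq_config"
  )
}

#' Read a configuration from JSON
#'
#' JSON keys mirror the [ccq_config()] arguments; the domain map is given as
#' `{"symptoms": [...], "mental": [...], "functional": [...]}`.  Absent keys
#' keep their defaults.
#'
#' @param path JSON file path.
#' @return A `ccq_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    ccq_validation_error(sprintf("config file not found: %s", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- if (!is.null(raw$domain_map)) {
    ccq_domain_map(raw$domain_map$symptoms, raw$domain_map$mental,
                   raw$domain_map$functional)
  } else {
    ccq_domain_map()
  }
  args <- raw[intersect(names(raw),
                        c("delta", "p", "denominator", "ci",
                          "missing_policy", "likert", "tdi_mode",
                          "domain_tables"))]
  do.call(ccq_config, c(list(domain_map = dm), args))
}

config_to_list <- function(config) {
  list(
    domain_map = lapply(unclass(config$domain_map), as.integer),
    delta = config$delta, p = config$p,
    denominator = config$denominator, ci = config$ci,
    missing_policy = config$missing_policy, likert = config$likert,
    tdi_mode = config$tdi_mode, domain_tables = config$domain_tables,
    icc_variant = config$icc_variant
  )
}

#' Load and reconcile a full study
#'
#' Reads the long-format ratings CSV and the review-design CSV, validates
#' and scores every form, and reconciles the dataset against the study
#' structure: exactly one patient form and one treating-clinician form per
#' subject, and reviewer forms matching the design's (patient, reviewer)
#' pairs exactly.
#'
#' Subjects are matched to design patient indices by the sorted order of
#' their ids; reviewer ids must be the design's reviewer indices.
#'
#' @param ratings_path path to the ratings CSV (see [read_ratings()]).
#' @param design_path path to the design CSV (see [write_design()]).
#' @param config a [ccq_config()].
#' @return An object of class `study_dataset`: scores split by role, the
#'   design, subject ids, the config, and the input file digests.
#' @export
load_study <- function(ratings_path, design_path, config = ccq_config()) {
  stopifnot(inherits(config, "ccq_config"))
  ratings <- read_ratings(ratings_path)
  design <- read_design(design_path)
  scores <- score_forms(ratings, map = config$domain_map,
                        missing_policy = config$missing_policy,
                        likert = config$likert)
  digests <- c(ratings = unname(tools::md5sum(ratings_path)),
               design = unname(tools::md5sum(design_path)))
  build_study_dataset(scores, design, config, digests)
}

# Assemble and reconcile a study_dataset from a scored long table.
build_study_dataset <- function(scores, design, config,
                                digests = c(ratings = NA_character_,
                                            design = NA_character_)) {
  subjects <- sort(unique(scores$subject_id))
  if (length(subjects) != design$n_patients) {
    ccq_reconciliation_error(sprintf(
      "dataset has %d subjects but the design expects %d",
      length(subjects), design$n_patients))
  }
  subject_index <- stats::setNames(seq_along(subjects), subjects)

  for (role in c("patient", "treating")) {
    tab <- table(scores$subject_id[scores$rater_role == role])
    missing <- subjects[!subjects %in% names(tab)]
    dup <- names(tab)[tab > 1]
    if (length(missing)) {
      ccq_reconciliation_error(sprintf(
        "missing %s form for subject(s): %s", role,
        paste(head(missing, 10), collapse = ", ")))
    }
    if (length(dup)) {
      ccq_reconciliation_error(sprintf(
        "duplicate %s form for subject(s): %s", role,
        paste(head(dup, 10), collapse = ", ")))
    }
  }

  rev_scores <- scores[scores$rater_role == "reviewer", , drop = FALSE]
  if (nrow(rev_scores) > 0 && anyNA(suppressWarnings(
        as.integer(rev_scores$rater_id)))) {
    ccq_reconciliation_error(
      "reviewer rater_id values must be the design's reviewer indices")
  }
  rev_tab <- data.frame(
    patient = unname(subject_index[rev_scores$subject_id]),
    reviewer = as.integer(rev_scores$rater_id),
    total = rev_scores$total, symptoms = rev_scores$symptoms,
    mental = rev_scores$mental, functional = rev_scores$functional
  )
  # aggregate_reviewers re-checks pair-level reconciliation and errors with
  # the offending (patient, reviewer) pairs
  reviewer_means <- aggregate_reviewers(rev_tab, design)

  by_role <- function(role) {
    sub <- scores[scores$rater_role == role, , drop = FALSE]
    sub[order(subject_index[sub$subject_id]), , drop = FALSE]
  }
  structure(
    list(
      subjects = subjects,
      patient = by_role("patient"),
      treating = by_role("treating"),
      reviewer = rev_tab,
      reviewer_means = reviewer_means,
      design = design,
      config = config,
      digests = digests
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Study dataset: %d subjects, %d patient + %d treating + %d reviewer forms (%d reviewers)\n",
    length(x$subjects), nrow(x$patient), nrow(x$treating), nrow(x$reviewer),
    x$design$n_reviewers))
  invisible(x)
}

comparison_labels <- c(
  patient_treating = "patient vs treating clinician",
  patient_reviewer_mean = "patient vs mean reviewing clinicians",
  treating_reviewer_mean = "treating clinician vs mean reviewing clinicians"
)

#' Run the three-comparison agreement analysis
#'
#' Computes the full agreement suite on total scores for the three pairwise
#' comparisons -- patient vs treating clinician, patient vs reviewer mean,
#' treating clinician vs reviewer mean -- plus Bland-Altman datasets for the
#' total and the three domain scores of the patient-vs-reviewer-mean
#' comparison, Shapiro-Wilk normality annotations for each total-score
#' series, and a run manifest.  Deterministic given the dataset and config.
#'
#' @param dataset a [load_study()] / [build_study_dataset()] result.
#' @param p,delta override the config's TDI proportion / CP half-width.
#' @return An object of class `study_report`: `agreement_table` (long data
#'   frame mirroring the published layout: comparison x statistic with
#'   estimate, one-sided 95% confidence limit, n, category),
#'   `bland_altman` (list: total, symptoms, mental, functional),
#'   `normality`, `estimates` (the raw `agreement_estimate` objects),
#'   `manifest`.
#' @export
run_study <- function(dataset, p = NULL, delta = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  cfg <- dataset$config
  p <- p %||% cfg$p
  delta <- delta %||% cfg$delta

  pt <- dataset$patient$total
  tt <- dataset$treating$total
  rt <- dataset$reviewer_means$total
  # with complete forms, the mean of reviewer totals must equal the total of
  # item-wise mean scores (linearity of the scoring rule); assert it
  wm <- (4 * dataset$reviewer_means$symptoms +
           2 * dataset$reviewer_means$mental +
           4 * dataset$reviewer_means$functional) / 10
  if (max(abs(wm - rt)) > 1e-9) {
    ccq_validation_error(
      "reviewer mean totals disagree with item-wise means; forms incomplete?")
  }

  series <- list(patient_treating = list(pt, tt),
                 patient_reviewer_mean = list(pt, rt),
                 treating_reviewer_mean = list(tt, rt))
  estimates <- lapply(series, function(s) {
    agreement_estimate(s[[1]], s[[2]], p = p, delta = delta,
                       ci = cfg$ci, denominator = cfg$denominator,
                       tdi_mode = cfg$tdi_mode)
  })

  agreement_table <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(
      comparison = comparison_labels[[nm]],
      statistic = c("CCC", "Precision", "Accuracy",
                    sprintf("TDI %.2g", p), sprintf("CP %.2g", delta), "ICC"),
      estimate = c(e$ccc, e$precision, e$accuracy, e$tdi, e$cp, e$icc),
      conf_limit_95 = c(e$ccc_lo, e$precision_lo, e$accuracy_lo, e$tdi_hi,
                        e$cp_lo, e$icc_lo),
      p = c(NA, NA, NA, p, NA, NA),
      delta = c(NA, NA, NA, NA, delta, NA),
      n = e$n,
      category = c(e$category, rep(NA_character_, 3),
                   NA_character_, categorize_agreement(e$icc)),
      stringsAsFactors = FALSE
    )
  }))

  ba <- list(
    total = bland_altman(pt, rt, delta = delta),
    symptoms = bland_altman(dataset$patient$symptoms,
                            dataset$reviewer_means$symptoms, delta = delta),
    mental = bland_altman(dataset$patient$mental,
                          dataset$reviewer_means$mental, delta = delta),
    functional = bland_altman(dataset$patient$functional,
                              dataset$reviewer_means$functional,
                              delta = delta)
  )

  normality <- lapply(
    list(patient_total = pt, treating_total = tt, reviewer_mean_total = rt),
    function(v) {
      tryCatch(normality_check(v),
               ccq_validation_error = function(e) {
                 list(W = NA_real_, p_value = NA_real_, normal = NA,
                      alpha = 0.05, n = length(v),
                      note = conditionMessage(e))
               })
    })

  domain_tables <- NULL
  if (cfg$domain_tables) {
    domain_tables <- do.call(rbind, lapply(
      c("symptoms", "mental", "functional"), function(dom) {
        e <- agreement_estimate(dataset$patient[[dom]],
                                dataset$reviewer_means[[dom]],
                                p = p, delta = delta, ci = cfg$ci,
                                denominator = cfg$denominator,
                                tdi_mode = cfg$tdi_mode)
        data.frame(domain = dom, ccc = e$ccc, ccc_lo = e$ccc_lo,
                   tdi = e$tdi, cp = e$cp, n = e$n,
                   stringsAsFactors = FALSE)
      }))
  }

  manifest <- list(
    n_subjects = length(dataset$subjects),
    n_reviewers = dataset$design$n_reviewers,
    reviews_per_patient = dataset$design$reviews_per_patient,
    design_seed = dataset$design$seed,
    p = p, delta = delta,
    config = config_to_list(cfg),
    input_digests = as.list(dataset$digests)
  )

  structure(
    list(agreement_table = agreement_table, bland_altman = ba,
         normality = normality, estimates = estimates,
         domain_tables = domain_tables, manifest = manifest),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Agreement between patient, treating clinician and reviewing clinicians\n")
  tab <- x$agreement_table
  tab$estimate <- round(tab$estimate, 3)
  tab$conf_limit_95 <- round(tab$conf_limit_95, 3)
  print(tab[c("comparison", "statistic", "estimate", "conf_limit_95",
              "category")], row.names = FALSE)
  nn <- vapply(x$normality, function(z) isTRUE(z$normal), logical(1))
  cat(sprintf("Shapiro-Wilk normality (alpha 0.05): %s\n",
              paste(sprintf("%s %s", names(nn),
                            ifelse(nn, "normal", "NON-NORMAL")),
                    collapse = ", ")))
  invisible(x)
}

#' Export a study report to files
#'
#' Writes `agreement.csv` and `agreement.json` (the three-comparison table),
#' four Bland-Altman CSVs (`bland_altman_total.csv`, `_symptoms.csv`,
#' `_mental.csv`, `_functional.csv` -- the panels of the difference-vs-mean
#' figure), and `manifest.json`.  Re-exporting the same report reproduces
#' byte-identical CSVs.
#'
#' @param report a [run_study()] result.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @export
export_report <- function(report, out_dir) {
  if (!inherits(report, "study_report") ||
      is.null(report$agreement_table) || nrow(report$agreement_table) == 0) {
    ccq_validation_error("refusing to export an empty or invalid report")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(out_dir, "agreement.csv")
  write.csv(report$agreement_table, p, row.names = FALSE, na = "")
  paths <- c(paths, p)

  p <- file.path(out_dir, "agreement.json")
  jsonlite::write_json(
    list(agreement_table = report$agreement_table,
         normality = report$normality),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, p)

  for (nm in names(report$bland_altman)) {
    b <- report$bland_altman[[nm]]
    p <- file.path(out_dir, sprintf("bland_altman_%s.csv", nm))
    df <- as.data.frame(b)
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
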