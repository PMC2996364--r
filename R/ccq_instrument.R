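#' Item-to-domain map for the CCQ
#'
#' The CCQ has 10 items in three domains: symptoms (4 items), mental state
#' (2 items) and functional state (4 items).  The default follows the
#' published CCQ convention (symptoms = items 1, 2, 5, 6; mental = 3, 4;
#' functional = 7--10), but any disjoint 4/2/4 partition of the items may be
#' supplied, since the agreement analysis is invariant to the labelling.
#'
#' @param symptoms,mental,functional integer item indices (1-based) of sizes
#'   4, 2 and 4; together they must cover 1..10 exactly once.
#' @return An object of class `ccq_domain_map`: a named list of the three
#'   index vectors.
#' @examples
#' ccq_domain_map()
#' @export
ccq_domain_map <- function(symptoms = c(1L, 2L, 5L, 6L),
                           mental = c(3L, 4L),
                           functional = c(7L, 8L, 9L, 10L)) {
  symptoms <- as.integer(symptoms)
  mental <- as.integer(mental)
  functional <- as.integer(functional)
  if (length(symptoms) != 4L || length(mental) != 2L || length(functional) != 4L) {
    ccq_validation_error(
      "domain map must have 4 symptoms, 2 mental and 4 functional items")
  }
  all_items <- c(symptoms, mental, functional)
  if (anyNA(all_items) || !setequal(all_items, 1:10) ||
      anyDuplicated(all_items) > 0L) {
    ccq_validation_error(
      "domain map must partition items 1..10 into disjoint sets")
  }
  structure(
    list(symptoms = symptoms, mental = mental, functional = functional),
    class = "ccq_domain_map"
  )
}

#' Construct a single completed CCQ form
#'
#' @param subject_id identifier of the respondent's subject (patient).
#' @param rater_role one of `"patient"`, `"treating"`, `"reviewer"`.
#' @param items numeric vector of the 10 item answers (0--6 Likert scale).
#' @param rater_id identifier of the rater; required for the reviewer role.
#' @return An object of class `ccq_form`.  Construction does not validate the
#'   answers; see [validate_ccq_form()].
#' @seealso [validate_ccq_form()], [score_ccq()]
#' @export
ccq_form <- function(subject_id, rater_role, items, rater_id = NA) {
  structure(
    list(
      subject_id = subject_id,
      rater_role = as.character(rater_role),
      rater_id = rater_id,
      items = as.numeric(items)
    ),
    class = "ccq_form"
  )
}

#' Validate a completed CCQ form
#'
#' Checks the form against the instrument's invariants: exactly 10 items,
#' every answered item an integer in 0..6 (7-point Likert scale), no missing
#' answers, and a rater id when the rater is a reviewer.  Violations are
#' reported, not raised, so a whole dataset can be screened in one pass.
#'
#' @param form a [ccq_form()].
#' @param likert if `TRUE` (default) items must be integers in 0..6; if
#'   `FALSE` any finite real answer is accepted (used for synthetic
#'   continuous-scale studies that skip Likert discretization).
#' @return A character vector of violation messages, empty when the form is
#'   valid.  Each item-level message names the offending item index.
#' @examples
#' validate_ccq_form(ccq_form("p1", "patient", rep(3, 10)))   # character(0)
#' validate_ccq_form(ccq_form("p1", "patient", c(rep(3, 9), 7)))
#' @export
validate_ccq_form <- function(form, likert = TRUE) {
  violations <- character(0)
  if (!inherits(form, "ccq_form")) {
    return("not a ccq_form object")
  }
  if (!form$rater_role %in% c("patient", "treating", "reviewer")) {
    violations <- c(violations, sprintf(
      "rater_role '%s' is not one of patient/treating/reviewer", form$rater_role))
  }
  if (identical(form$rater_role, "reviewer") &&
      (length(form$rater_id) != 1L || is.na(form$rater_id))) {
    violations <- c(violations, "reviewer form is missing rater_id")
  }
  items <- form$items
  if (length(items) != 10L) {
    violations <- c(violations, sprintf(
      "form has %d items, expected exactly 10", length(items)))
    return(violations)
  }
  for (i in seq_along(items)) {
    v <- items[i]
    if (is.na(v)) {
      violations <- c(violations, sprintf("item %d is missing", i))
    } else if (!is.finite(v)) {
      violations <- c(violations, sprintf("item %d is not finite", i))
    } else if (likert && (v != round(v) || v < 0 || v > 6)) {
      violations <- c(violations, sprintf(
        "item %d = %s is outside the 0..6 integer Likert range", i,
        format(v)))
    }
  }
  violations
}

#' Score a CCQ form
#'
#' The CCQ total score is the mean of the 10 item answers; each domain score
#' is the mean of that domain's items.  All scores live on the 0--6 item
#' scale, and the total equals the item-count-weighted mean of the domain
#' scores, `(4*symptoms + 2*mental + 4*functional)/10`.
#'
#' Missing items: by default a form with any missing answer is refused.  With
#' `missing_policy = "prorate"`, a form is scored from pro-rated domain means
#' provided at least 8 of the 10 items are answered and every domain retains
#' at least half of its items; the total is then the 4/2/4-weighted mean of
#' the pro-rated domain scores.
#'
#' @param form a [ccq_form()].
#' @param map a [ccq_domain_map()].
#' @param missing_policy `"strict"` (default) or `"prorate"`.
#' @param likert passed to [validate_ccq_form()].
#' @return An object of class `ccq_score`: list with `total`, `symptoms`,
#'   `mental`, `functional`.
#' @examples
#' score_ccq(ccq_form("p1", "patient", c(0, 1, 2, 3, 4, 5, 6, 0, 1, 2)))
#' @export
score_ccq <- function(form, map = ccq_domain_map(),
                      missing_policy = c("strict", "prorate"),
                      likert = TRUE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(map, "ccq_domain_map"))
  violations <- validate_ccq_form(form, likert = likert)
  missing_only <- grepl("is missing$", violations)
  if (any(!missing_only)) {
    ccq_validation_error(paste0(
      "cannot score invalid form: ", paste(violations[!missing_only],
                                           collapse = "; ")))
  }
  items <- form$items
  if (any(missing_only)) {
    if (missing_policy == "strict") {
      ccq_validation_error(paste0(
        "cannot score incomplete form under the strict policy: ",
        paste(violations[missing_only], collapse = "; ")))
    }
    if (sum(!is.na(items)) < 8L) {
      ccq_validation_error(
        "cannot pro-rate: fewer than 8 of 10 items answered")
    }
    for (dom in names(map)) {
      present <- sum(!is.na(items[map[[dom]]]))
      if (present * 2L < length(map[[dom]])) {
        ccq_validation_error(sprintf(
          "cannot pro-rate: %s domain has only %d of %d items answered",
          dom, present, length(map[[dom]])))
      }
    }
  }
  dom_means <- vapply(map, function(idx) mean(items[idx], na.rm = TRUE),
                      numeric(1))
  # total as the item-count-weighted mean of domain means: identical to
  # mean(items) for complete forms, and keeps the weighted-mean invariant
  # exact under pro-rating.
  weights <- vapply(map, length, integer(1))
  total <- sum(weights * dom_means) / sum(weights)
  structure(
    list(
      total = total,
      symptoms = dom_means[["symptoms"]],
      mental = dom_means[["mental"]],
      functional = dom_means[["functional"]]
    ),
    class = "ccq_score"
  )
}

#' @export
print.ccq_score <- function(x, ...) {
  cat(sprintf(
    "CCQ score: total %.2f (symptoms %.2f, mental %.2f, functional %.2f)\n",
    x$total, x$symptoms, x$mental, x$functional))
  invisible(x)
}

#' Score a long-format table of CCQ forms
#'
#' @param ratings data frame with columns `subject_id`, `rater_role`,
#'   `rater_id`, `item_1` .. `item_10` (one row per completed form), as read
#'   by [read_ratings()].
#' @inheritParams score_ccq
#' @return A data frame with one row per form: `subject_id`, `rater_role`,
#'   `rater_id`, `total`, `symptoms`, `mental`, `functional`.
#' @export
score_forms <- function(ratings, map = ccq_domain_map(),
                        missing_policy = c("strict", "prorate"),
                        likert = TRUE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(map, "ccq_domain_map"))
  required <- c("subject_id", "rater_role", "rater_id", item_cols)
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    ccq_validation_error(paste0(
      "ratings table is missing columns: ",
      paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(ratings[item_cols])
  storage.mode(m) <- "double"

  # rows that the vectorized path cannot handle (missing / out-of-range
  # items, bad roles) are delegated to score_ccq for a row-indexed message
  bad_role <- !ratings$rater_role %in% c("patient", "treating", "reviewer") |
    (ratings$rater_role == "reviewer" & is.na(ratings$rater_id))
  bad_item <- rowSums(is.na(m) | !is.finite(m)) > 0
  if (likert) {
    bad_item <- bad_item |
      rowSums(m != round(m) | m < 0 | m > 6, na.rm = TRUE) > 0
  }
  slow <- which(bad_role | bad_item)

  dom <- vapply(names(map), function(d) rowMeans(m[, map[[d]], drop = FALSE]),
                numeric(nrow(m)))
  dom <- matrix(dom, nrow = nrow(m),
                dimnames = list(NULL, names(map)))
  out <- data.frame(
    subject_id = as.character(ratings$subject_id),
    rater_role = as.character(ratings$rater_role),
    rater_id = as.character(ratings$rater_id),
    total = (4 * dom[, "symptoms"] + 2 * dom[, "mental"] +
               4 * dom[, "functional"]) / 10,
    symptoms = dom[, "symptoms"], mental = dom[, "mental"],
    functional = dom[, "functional"],
    stringsAsFactors = FALSE
  )
  for (i in slow) {
    form <- ccq_form(ratings$subject_id[i], ratings$rater_role[i],
                     m[i, ], rater_id = ratings$rater_id[i])
    s <- tryCatch(
      score_ccq(form, map = map, missing_policy = missing_policy,
                likert = likert),
      ccq_validation_error = function(e) {
        ccq_validation_error(sprintf("row %d: %s", i, conditionMessage(e)))
      })
    out$total[i] <- s$total
    out$symptoms[i] <- s$symptoms
    out$mental[i] <- s$mental
    out$functional[i] <- s$functional
  }
  out
}

item_cols <- paste0("item_", 1:10)

ratings_to_forms <- function(ratings) {
  required <- c("subject_id", "rater_role", "rater_id", item_cols)
  missing_cols <- setdiff(required, names(ratings))
  if (length(missing_cols) > 0) {
    ccq_validation_error(paste0(
      "ratings table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  lapply(seq_len(nrow(ratings)), function(i) {
    ccq_form(
      subject_id = ratings$subject_id[i],
      rater_role = ratings$rater_role[i],
      rater_id = ratings$rater_id[i],
      items = as.numeric(ratings[i, item_cols])
    )
  })
}

#' Read / write a long-format CCQ ratings CSV
#'
#' One row per completed form; columns `subject_id`, `rater_role`,
#' `rater_id`, `item_1` .. `item_10`.  Header required, UTF-8, missing cells
#' empty.
#'
#' @param path CSV file path.
#' @return `read_ratings()`: the ratings data frame with `rater_id` as
#'   character (`NA` where empty).
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    ccq_validation_error(sprintf("ratings file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                 encoding = "UTF-8")
  required <- c("subject_id", "rater_role", "rater_id", item_cols)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    ccq_validation_error(paste0(
      "malformed ratings CSV, missing columns: ",
      paste(missing_cols, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  df$rater_id <- as.character(df$rater_id)
  df
}

#' @rdname read_ratings
#' @param ratings ratings data frame.
#' @export
write_ratings <- function(ratings, path) {
  write.csv(ratings, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
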