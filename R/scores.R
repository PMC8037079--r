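# Score calculators: GERtality, GTOS, ISS, max AIS.

#' Construct a score definition
#'
#' An additive score is an ordered list of named binary criteria, each worth
#' one point; the score ranges from 0 to the number of criteria.
#'
#' @param name Score name.
#' @param criteria List of criteria as produced by [make_criterion()].
#' @return Object of class `score_definition`.
#' @export
score_definition <- function(name, criteria) {
  nm <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("criteria names must be unique", call. = FALSE)
  structure(list(name = name, criteria = criteria), class = "score_definition")
}

#' Define a single binary criterion over patient records
#'
#' @param variable One of `age`, `max_ais`, `transfusion`, `asa`, `gcs`,
#'   `sex_male`, `mechanism_high_energy`, `sbp`.
#' @param direction `"ge"` (variable >= cutoff), `"le"` (variable <= cutoff)
#'   or `"true"` (boolean variable itself).
#' @param cutoff Numeric cut-off; ignored for direction `"true"`.
#' @return A criterion (named list) usable in [score_definition()].
#' @export
make_criterion <- function(variable, direction = c("ge", "le", "true"),
                           cutoff = NA_real_) {
  direction <- match.arg(direction)
  known <- c("age", "max_ais", "transfusion", "asa", "gcs", "sex_male",
             "mechanism_high_energy", "sbp")
  if (!variable %in% known) {
    stop(sprintf("unknown criterion variable '%s'", variable), call. = FALSE)
  }
  op <- switch(direction, ge = ">=", le = "<=", true = "")
  name <- if (direction == "true") variable
          else sprintf("%s%s%g", variable, op, cutoff)
  list(name = name, variable = variable, direction = direction,
       cutoff = cutoff)
}

#' @noRd
criterion_values <- function(variable, records) {
  switch(variable,
    age = as.numeric(records$age),
    max_ais = as.numeric(max_ais(records)),
    asa = as.numeric(records$asa),
    gcs = as.numeric(records$gcs),
    sbp = as.numeric(records$sbp),
    transfusion = records$prbc_pre_icu,
    sex_male = ifelse(records$sex == "unknown", NA, records$sex == "male"),
    mechanism_high_energy = ifelse(
      records$mechanism == "unknown", NA,
      records$mechanism %in% c("traffic", "high_fall", "penetrating")),
    stop(sprintf("unknown criterion variable '%s'", variable), call. = FALSE))
}

#' Evaluate a criterion on patient records
#'
#' @param criterion A [make_criterion()] object.
#' @param records Data frame of patient records.
#' @return Character vector with values `"met"`, `"not_met"` or `"unknown"`
#'   (unknown when the underlying field is missing).
#' @export
criterion_status <- function(criterion, records) {
  v <- criterion_values(criterion$variable, records)
  hit <- switch(criterion$direction,
                ge = v >= criterion$cutoff,
                le = v <= criterion$cutoff,
                true = as.logical(v))
  ifelse(is.na(hit), "unknown", ifelse(hit, "met", "not_met"))
}

#' The five GERtality criteria
#'
#' Returns the GERtality score definition: one point each for age >= 80
#' years, maximum AIS in any body region >= 4, packed red-blood-cell
#' transfusion before ICU admission, pre-injury ASA physical status >= 3,
#' and GCS <= 13 (equivalently GCS < 14). The score therefore ranges from
#' 0 to 5 points.
#'
#' @return A [score_definition()] with exactly five criteria in that order.
#' @export
#' @examples
#' length(gertality_criteria()$criteria)  # 5
gertality_criteria <- function() {
  score_definition("GERtality", list(
    make_criterion("age", "ge", 80),
    make_criterion("max_ais", "ge", 4),
    make_criterion("transfusion", "true"),
    make_criterion("asa", "ge", 3),
    make_criterion("gcs", "le", 13)))
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score '%s'> %d one-point criteria (range 0-%d)\n",
              x$name, length(x$criteria), length(x$criteria)))
  for (cr in x$criteria) cat("  -", cr$name, "\n")
  invisible(x)
}

#' Evaluate all criteria of a score on patient records
#'
#' @param definition A [score_definition()].
#' @param records Data frame of patient records.
#' @return Character matrix (`nrow(records)` x criteria) of
#'   `"met"/"not_met"/"unknown"`, columns named by criterion.
#' @export
evaluate_criteria <- function(definition, records) {
  out <- vapply(definition$criteria,
                function(cr) criterion_status(cr, records),
                character(nrow(records)))
  out <- matrix(out, nrow = nrow(records),
                dimnames = list(NULL,
                                vapply(definition$criteria, `[[`,
                                       character(1), "name")))
  out
}

#' Compute an additive score from a definition
#'
#' @param definition A [score_definition()].
#' @param records Data frame of patient records.
#' @param missing_policy How to treat criteria that cannot be evaluated
#'   because a field is missing: `"zero_points"` (default; an unknown
#'   criterion contributes 0, so the score is computable with partial data)
#'   or `"propagate_missing"` (any unknown criterion makes the total
#'   missing, for complete-case analyses).
#' @return Integer vector of points in \[0, number of criteria\], `NA` where
#'   the policy propagates missingness.
#' @export
score_records <- function(definition, records,
                          missing_policy = c("zero_points",
                                             "propagate_missing")) {
  missing_policy <- match.arg(missing_policy)
  status <- evaluate_criteria(definition, records)
  pts <- rowSums(status == "met")
  if (missing_policy == "propagate_missing") {
    pts[rowSums(status == "unknown") > 0] <- NA_integer_
  }
  as.integer(pts)
}

#' GERtality score
#'
#' One point per met GERtality criterion (see [gertality_criteria()]);
#' total in 0-5.
#'
#' @inheritParams score_records
#' @return Integer vector 0-5, `NA` under `propagate_missing` when a
#'   component is unknown.
#' @export
#' @examples
#' rec <- data.frame(patient_id = "p", age = 85, ais_head_neck = 5,
#'                   ais_face = 0, ais_chest = 0, ais_abdomen = 0,
#'                   ais_extremities = 0, ais_external = 0, gcs = 3,
#'                   asa = 4, prbc_pre_icu = TRUE, icu_admitted = TRUE,
#'                   died_in_hospital = FALSE)
#' gertality_score(validate_records(rec))  # 5
gertality_score <- function(records,
                            missing_policy = c("zero_points",
                                               "propagate_missing")) {
  score_records(gertality_criteria(), records, missing_policy)
}

#' Injury Severity Score (ISS)
#'
#' Sum of squares of the three highest regional AIS severities over the six
#' ISS body regions; any region graded AIS 6 sets the ISS to 75 by
#' convention. Result in \[0, 75\].
#'
#' @param records Data frame of patient records with the six `ais_*`
#'   columns.
#' @return Integer vector of ISS values.
#' @export
#' @examples
#' rec <- worked_fixture()$records
#' iss(rec)
iss <- function(records) {
  m <- as.matrix(records[, ais_columns(), drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(is.na(m)) || any(m < 0 | m > 6)) {
    stop("AIS values must be present and lie in [0, 6]", call. = FALSE)
  }
  top3 <- apply(m, 1L, function(v) sum(sort(v, decreasing = TRUE)[1:3]^2))
  out <- as.integer(ifelse(apply(m, 1L, max) == 6, 75L, top3))
  out
}

#' Geriatric Trauma Outcome Score (GTOS)
#'
#' GTOS = age + 2.5 x ISS + 22 if packed red blood cells were given. Only
#' the score value is computed; the original logistic mapping from GTOS to a
#' mortality probability is not part of this package.
#'
#' @param records Data frame of patient records.
#' @return Numeric vector; `NA` where the transfusion flag is missing.
#' @export
#' @examples
#' # age 80, ISS 50, transfused: 80 + 125 + 22 = 227
gtos <- function(records) {
  records$age + 2.5 * iss(records) + 22 * as.numeric(records$prbc_pre_icu)
}

#' Score every record of a cohort
#'
#' Applies all per-record calculators and returns one row per patient with
#' the GERtality points and per-criterion component status, GTOS, ISS and
#' maximum AIS, plus the fields needed downstream (age, outcome).
#'
#' @param cohort A (typically filtered) cohort.
#' @inheritParams score_records
#' @return Data frame with columns `patient_id`, `gertality`,
#'   `comp_<criterion>` (five columns), `gtos`, `iss`, `max_ais`, `age`,
#'   `died_in_hospital`.
#' @export
score_cohort <- function(cohort,
                         missing_policy = c("zero_points",
                                            "propagate_missing")) {
  stopifnot(inherits(cohort, "gertality_cohort"))
  missing_policy <- match.arg(missing_policy)
  rec <- cohort$records
  def <- gertality_criteria()
  if (nrow(rec) == 0L) {
    out <- data.frame(patient_id = character(), gertality = integer())
    for (cr in def$criteria) out[[paste0("comp_", cr$variable)]] <- character()
    out$gtos <- numeric(); out$iss <- integer(); out$max_ais <- integer()
    out$age <- integer(); out$died_in_hospital <- logical()
    return(out)
  }
  comp <- evaluate_criteria(def, rec)
  out <- data.frame(patient_id = rec$patient_id,
                    gertality = score_records(def, rec, missing_policy),
                    stringsAsFactors = FALSE)
  for (i in seq_along(def$criteria)) {
    out[[paste0("comp_", def$criteria[[i]]$variable)]] <- comp[, i]
  }
  out$gtos <- gtos(rec)
  out$iss <- iss(rec)
  out$max_ais <- max_ais(rec)
  out$age <- rec$age
  out$died_in_hospital <- rec$died_in_hospital
  out
}
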