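# Registry model: patient records, CSV I/O, and the cohort inclusion filter.

#' The six ISS body regions
#'
#' Body regions over which AIS severities are recorded, in the fixed order
#' used throughout the package. The ISS is defined over exactly these six
#' regions (head/neck, face, chest, abdomen, extremities including pelvis,
#' external/skin).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' ais_regions()
ais_regions <- function() {
  c("head_neck", "face", "chest", "abdomen", "extremities", "external")
}

#' @noRd
ais_columns <- function() paste0("ais_", ais_regions())

sex_levels <- c("male", "female", "unknown")
mechanism_levels <- c("traffic", "low_fall", "high_fall", "penetrating",
                      "other", "unknown")
transfer_levels <- c("primary", "transfer_in", "early_transfer_out")
region_levels <- c("europe", "non_europe")
exclusion_levels <- c("under_65", "non_european", "transfer",
                      "missing_transfusion_data", "minor_trauma_no_icu")

#' @noRd
canonical_columns <- function() {
  c("patient_id", "age", "sex", ais_columns(), "gcs", "asa", "sbp",
    "prbc_pre_icu", "icu_admitted", "mechanism", "transfer_status",
    "region_of_hospital", "died_in_hospital", "los")
}

#' @noRd
required_columns <- function() {
  c("patient_id", "age", ais_columns(), "died_in_hospital")
}

#' Validate and normalize a data frame of patient records
#'
#' Checks ranges (AIS in 0-6, GCS in 3-15 when present, ASA in 1-4 when
#' present), fills absent optional columns with missing values or neutral
#' defaults, and coerces column types.
#'
#' @param records Data frame with (a subset of) the canonical columns.
#' @return Data frame with all canonical columns, one row per patient.
#' @export
validate_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in required_columns()) {
    if (!col %in% names(records)) {
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
    }
  }
  col <- function(name) {
    if (name %in% names(records)) records[[name]]
    else rep(NA, nrow(records))
  }
  out <- data.frame(patient_id = as.character(records$patient_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$patient_id)) {
    stop("duplicate patient_id values", call. = FALSE)
  }
  out$age <- parse_integer(records$age, "age", required = TRUE)
  if (any(out$age < 0)) stop("age must be >= 0", call. = FALSE)
  out$sex <- parse_enum(col("sex"), sex_levels, "sex",
                        default = "unknown")
  for (ac in ais_columns()) {
    v <- parse_integer(records[[ac]], ac, required = TRUE)
    if (any(v < 0 | v > 6)) {
      stop(sprintf("AIS values in '%s' must lie in [0, 6]", ac),
           call. = FALSE)
    }
    out[[ac]] <- v
  }
  out$gcs <- parse_integer(col("gcs"), "gcs")
  if (any(!is.na(out$gcs) & (out$gcs < 3 | out$gcs > 15))) {
    stop("gcs must lie in [3, 15] when present", call. = FALSE)
  }
  out$asa <- parse_integer(col("asa"), "asa")
  if (any(!is.na(out$asa) & (out$asa < 1 | out$asa > 4))) {
    stop("asa must lie in [1, 4] when present", call. = FALSE)
  }
  out$sbp <- parse_integer(col("sbp"), "sbp")
  out$prbc_pre_icu <- parse_boolean(col("prbc_pre_icu"))
  out$icu_admitted <- parse_boolean(col("icu_admitted"))
  out$mechanism <- parse_enum(col("mechanism"), mechanism_levels,
                              "mechanism", default = "unknown")
  out$transfer_status <- parse_enum(col("transfer_status"),
                                    transfer_levels, "transfer_status",
                                    default = "primary")
  out$region_of_hospital <- parse_enum(col("region_of_hospital"),
                                       region_levels, "region_of_hospital",
                                       default = "europe")
  died <- parse_boolean(records$died_in_hospital)
  if (any(is.na(died))) {
    stop("required field 'died_in_hospital' has missing values", call. = FALSE)
  }
  out$died_in_hospital <- died
  out$los <- suppressWarnings(as.numeric(col("los")))
  out
}

#' Construct a cohort object
#'
#' A cohort bundles the included patient records with an exclusion log so
#' that every input record is accounted for exactly once: counts are
#' conserved across filtering.
#'
#' @param records Data frame of patient records (see [validate_records()]).
#' @param exclusion_log Data frame with columns `patient_id` and `reason`
#'   (one of `r paste(exclusion_levels, collapse = ", ")`), empty by default.
#' @return Object of class `gertality_cohort`.
#' @export
new_cohort <- function(records,
                       exclusion_log = data.frame(patient_id = character(),
                                                  reason = character(),
                                                  stringsAsFactors = FALSE)) {
  records <- validate_records(records)
  stopifnot(all(c("patient_id", "reason") %in% names(exclusion_log)))
  if (nrow(exclusion_log) &&
      !all(exclusion_log$reason %in% exclusion_levels)) {
    stop("unknown exclusion reason", call. = FALSE)
  }
  if (any(exclusion_log$patient_id %in% records$patient_id)) {
    stop("a patient cannot be both included and excluded", call. = FALSE)
  }
  structure(list(records = records,
                 exclusion_log = as.data.frame(exclusion_log)),
            class = "gertality_cohort")
}

#' @export
print.gertality_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d included record(s), %d excluded\n",
              nrow(x$records), nrow(x$exclusion_log)))
  if (nrow(x$exclusion_log)) {
    tab <- table(x$exclusion_log$reason)
    for (r in names(tab)) cat(sprintf("  excluded %-25s %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Read a patient-level cohort from CSV
#'
#' Reads one patient per row. Booleans accept `1/0`, `true/false`, `yes/no`;
#' empty cells are missing. Unparseable values in optional fields become
#' missing; unparseable values in required fields (age, AIS, outcome) are an
#' error. Column names in the file can differ from the canonical names via
#' `column_map`.
#'
#' @param path Path to a CSV file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(age = "patient_age")`. Unmapped columns are looked up by their
#'   canonical name.
#' @return A [new_cohort()] object with an empty exclusion log.
#' @export
read_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("empty file: no data rows", call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      file_col <- column_map[[canon]]
      if (!file_col %in% names(raw)) {
        stop(sprintf("mapped column '%s' (for '%s') not found in file",
                     file_col, canon), call. = FALSE)
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  for (col in required_columns()) {
    if (!col %in% names(raw)) {
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
    }
  }
  new_cohort(raw[, intersect(canonical_columns(), names(raw)), drop = FALSE])
}

#' Write a cohort's records (and exclusion log) to CSV
#'
#' @param cohort A cohort object.
#' @param path Output CSV path for the included records.
#' @param exclusion_path Optional path for the exclusion log
#'   (`patient_id, reason`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, exclusion_path = NULL) {
  stopifnot(inherits(cohort, "gertality_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "")
  if (!is.null(exclusion_path)) {
    utils::write.csv(cohort$exclusion_log, exclusion_path,
                     row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Maximum AIS across the six body regions
#'
#' @param records Data frame of patient records.
#' @return Integer vector in \[0, 6\], one value per record.
#' @export
#' @examples
#' rec <- worked_fixture()$records[1, ]
#' max_ais(rec)
max_ais <- function(records) {
  do.call(pmax, c(unname(as.list(records[, ais_columns(), drop = FALSE])),
                  list(na.rm = FALSE)))
}

#' Apply the geriatric-trauma inclusion/exclusion filter
#'
#' Keeps patients aged 65 or older, treated in a European hospital, admitted
#' primarily (no transfer in or early transfer out), with known pre-ICU
#' transfusion status, and with either relevant trauma (maximum AIS >= 3) or
#' minor trauma (maximum AIS <= 2) that still required intensive care.
#' Every removed record is logged with the first matching reason in the
#' fixed precedence order: under_65, non_european, transfer,
#' missing_transfusion_data, minor_trauma_no_icu.
#'
#' @param cohort An unfiltered cohort.
#' @param require_european Apply the European-hospital criterion
#'   (disable for synthetic cohorts that do not model hospital region).
#' @param require_primary Apply the no-transfer criterion.
#' @return A filtered cohort; `|included| + |excluded|` equals the input
#'   count, and filtering an already-filtered cohort removes nothing.
#' @export
apply_inclusion_filter <- function(cohort, require_european = TRUE,
                                   require_primary = TRUE) {
  stopifnot(inherits(cohort, "gertality_cohort"))
  rec <- cohort$records
  mais <- max_ais(rec)
  icu <- !is.na(rec$icu_admitted) & rec$icu_admitted
  reason <- rep(NA_character_, nrow(rec))
  pick <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- pick(rec$age < 65, "under_65")
  if (require_european) {
    reason <- pick(rec$region_of_hospital != "europe", "non_european")
  }
  if (require_primary) {
    reason <- pick(rec$transfer_status != "primary", "transfer")
  }
  reason <- pick(is.na(rec$prbc_pre_icu), "missing_transfusion_data")
  reason <- pick(mais <= 2 & !icu, "minor_trauma_no_icu")
  keep <- is.na(reason)
  log_new <- data.frame(patient_id = rec$patient_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  new_cohort(rec[keep, , drop = FALSE],
             rbind(cohort$exclusion_log, log_new))
}

#' Summarize a filtered cohort
#'
#' Produces the usual registry baseline table: mean/median/SD of age, ISS,
#' number of injured regions and length of stay (when present), plus counts
#' and percentages (rounded to one decimal) of male sex, mechanism classes,
#' severe head injury (head/neck AIS >= 3), ICU treatment, and hospital
#' mortality.
#'
#' @param cohort A cohort with at least one record.
#' @return A list with elements `n`, `continuous` (data frame) and
#'   `categorical` (data frame with `count` and `percent`).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "gertality_cohort"))
  rec <- cohort$records
  if (nrow(rec) == 0L) stop("cannot summarize an empty cohort", call. = FALSE)
  n <- nrow(rec)
  iss_v <- iss(rec)
  n_injured <- rowSums(rec[, ais_columns(), drop = FALSE] > 0)
  cont_row <- function(name, v) {
    v <- v[!is.na(v)]
    data.frame(measure = name,
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               sd = if (length(v)) stats::sd(v) else NA_real_)
  }
  continuous <- rbind(cont_row("age", rec$age),
                      cont_row("iss", iss_v),
                      cont_row("injured_regions", n_injured),
                      cont_row("length_of_stay", rec$los))
  cat_row <- function(name, flag) {
    k <- sum(flag, na.rm = TRUE)
    data.frame(measure = name, count = k, percent = round(100 * k / n, 1))
  }
  categorical <- rbind(
    cat_row("male_sex", rec$sex == "male"),
    do.call(rbind, lapply(setdiff(mechanism_levels, "unknown"), function(m) {
      cat_row(paste0("mechanism_", m), rec$mechanism == m)
    })),
    cat_row("severe_head_injury", rec$ais_head_neck >= 3),
    cat_row("icu_treatment", rec$icu_admitted),
    cat_row("hospital_mortality", rec$died_in_hospital))
  list(n = n, continuous = continuous, categorical = categorical)
}
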