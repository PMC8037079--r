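# Score development: dichotomization, 2x2 tables, odds-ratio screening,
# cut-off search, and criterion selection.

candidate_order <- c("age", "max_ais", "transfusion", "asa", "gcs",
                     "sex_male", "mechanism_high_energy", "sbp")

#' Build a 2x2 mortality contingency table
#'
#' Cross-tabulates a dichotomized predictor (exposed / unexposed) against
#' in-hospital death. Records for which the predictor cannot be evaluated
#' (missing inputs) are dropped and counted in `n_dropped`; every counted
#' record must have a non-missing outcome.
#'
#' @param records Data frame of patient records (or a cohort, whose included
#'   records are used).
#' @param exposed A [make_criterion()] object, or a logical vector aligned
#'   with the records (`NA` = unevaluable).
#' @param label_exposed,label_unexposed Row labels for printing.
#' @return Object of class `contingency_2x2` with integer cells `a`
#'   (exposed, died), `b` (exposed, survived), `c` (unexposed, died), `d`
#'   (unexposed, survived).
#' @export
contingency <- function(records, exposed, label_exposed = "exposed",
                        label_unexposed = "unexposed") {
  if (inherits(records, "gertality_cohort")) records <- records$records
  if (is.list(exposed) && !is.null(exposed$variable)) {
    label_exposed <- exposed$name
    status <- criterion_status(exposed, records)
    exposed <- ifelse(status == "unknown", NA, status == "met")
  }
  stopifnot(is.logical(exposed), length(exposed) == nrow(records))
  died <- records$died_in_hospital
  if (any(is.na(died[!is.na(exposed)]))) {
    stop("counted records must have a non-missing outcome", call. = FALSE)
  }
  keep <- !is.na(exposed)
  e <- exposed[keep]; y <- died[keep]
  structure(list(a = sum(e & y), b = sum(e & !y),
                 c = sum(!e & y), d = sum(!e & !y),
                 n_dropped = sum(!keep),
                 label_exposed = label_exposed,
                 label_unexposed = label_unexposed),
            class = "contingency_2x2")
}

#' Construct a 2x2 table from raw cell counts
#'
#' @param a,b,c,d Cell counts: exposed-died, exposed-survived,
#'   unexposed-died, unexposed-survived.
#' @inheritParams contingency
#' @return A `contingency_2x2` object.
#' @export
contingency_from_counts <- function(a, b, c, d, label_exposed = "exposed",
                                    label_unexposed = "unexposed") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 n_dropped = 0L, label_exposed = label_exposed,
                 label_unexposed = label_unexposed),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c(x$label_exposed, x$label_unexposed),
                              c("died", "survived")))
  print(m)
  if (x$n_dropped) cat(sprintf("(%d unevaluable record(s) dropped)\n",
                               x$n_dropped))
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' Computes the cross-product odds ratio `OR = ((a+k)(d+k)) / ((b+k)(c+k))`
#' with optional continuity correction `k` (Haldane-Anscombe `k = 0.5` for
#' zero cells; the default `k = 0` is the crude OR). The 95% Wald interval
#' is `exp(log(OR) +/- z * SE)` with
#' `SE = sqrt(1/(a+k) + 1/(b+k) + 1/(c+k) + 1/(d+k))`. Equivalently,
#' `OR = (p1/(1-p1)) / (p2/(1-p2))` for the two group mortality proportions.
#' A zero cell with `k = 0` yields an infinite or zero OR with an undefined
#' CI, flagged rather than silently dropped.
#'
#' @param table A `contingency_2x2` object.
#' @param continuity Continuity correction `k` added to every cell
#'   (default 0).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return Object of class `odds_ratio_result` with elements `or`, `ci_low`,
#'   `ci_high`, `se_log`, `mortality_exposed`, `mortality_unexposed`,
#'   `n_exposed`, `n_unexposed`, `zero_cell`.
#' @export
odds_ratio <- function(table, continuity = 0, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  k <- continuity
  a <- table$a + k; b <- table$b + k; cc <- table$c + k; d <- table$d + k
  zero_cell <- any(c(a, b, cc, d) == 0)
  or <- (a * d) / (b * cc)
  if (zero_cell) {
    ci <- c(NA_real_, NA_real_); se <- NA_real_
  } else {
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  }
  ne <- table$a + table$b; nu <- table$c + table$d
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2], se_log = se,
                 mortality_exposed = if (ne > 0) table$a / ne else NA_real_,
                 mortality_unexposed = if (nu > 0) table$c / nu else NA_real_,
                 n_exposed = ne, n_unexposed = nu,
                 zero_cell = zero_cell, conf_level = conf_level,
                 continuity = k),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f), mortality %.1f%% vs %.1f%%%s\n",
              x$or, 100 * x$conf_level, x$ci_low, x$ci_high,
              100 * x$mortality_exposed, 100 * x$mortality_unexposed,
              if (x$zero_cell) " [zero cell: CI undefined]" else ""))
  invisible(x)
}

#' Search a cut-off grid for a target exposed-group mortality
#'
#' For a continuous registry variable, finds the least extreme cut-off on a
#' candidate grid whose exposed group reaches the target mortality (default
#' 30%; values around 25-30% are typical for this style of score
#' development). "Least extreme" means the smallest cut-off for `"ge"`
#' dichotomies and the largest for `"le"`, i.e. the qualifying cut-off that
#' exposes the most patients.
#'
#' @param records Data frame of patient records (or a cohort).
#' @param variable Criterion variable name (see [make_criterion()]).
#' @param candidate_cutoffs Non-empty numeric grid of cut-offs to try.
#' @param direction `"ge"` or `"le"`.
#' @param target_mortality Required exposed-group mortality proportion.
#' @return The chosen cut-off, or `NULL` if no cut-off qualifies.
#' @export
cutoff_search <- function(records, variable, candidate_cutoffs,
                          direction = c("ge", "le"),
                          target_mortality = 0.30) {
  if (inherits(records, "gertality_cohort")) records <- records$records
  direction <- match.arg(direction)
  if (!length(candidate_cutoffs)) stop("empty cut-off grid", call. = FALSE)
  check_prob(target_mortality, "target_mortality")
  grid <- sort(unique(candidate_cutoffs),
               decreasing = (direction == "le"))  # least extreme first
  for (cut in grid) {
    tab <- contingency(records, make_criterion(variable, direction, cut))
    n_exp <- tab$a + tab$b
    if (n_exp > 0 && tab$a / n_exp >= target_mortality) return(cut)
  }
  NULL
}

#' Multivariable logistic model for dichotomized predictors
#'
#' Fits a maximum-likelihood logistic regression of in-hospital death on a
#' set of binary predictors (iteratively reweighted least squares via
#' [stats::glm()], up to 100 iterations) and reports the exponentiated
#' coefficients as multivariable odds ratios. Separation or non-convergence
#' raises a diagnostic error rather than returning a silent result.
#'
#' @param predictors Data frame or matrix of binary (logical or 0/1)
#'   predictors, one column per candidate criterion.
#' @param outcome Logical vector of in-hospital death.
#' @return List with `coefficients` (including intercept), `se`, `or`
#'   (exponentiated non-intercept coefficients), `or_ci` (Wald 95% CI
#'   matrix), `n`, `converged`.
#' @export
logistic_fit <- function(predictors, outcome) {
  x <- as.data.frame(predictors)
  x[] <- lapply(x, function(v) as.numeric(v))
  y <- as.logical(outcome)
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y); p <- ncol(x)
  if (n < 10 * (p + 1)) {
    stop(sprintf("too few observations (%d) for %d predictors", n, p),
         call. = FALSE)
  }
  if (any(vapply(x, function(v) length(unique(v)) < 2, logical(1)))) {
    stop("constant predictor column", call. = FALSE)
  }
  dat <- cbind(x, .y = y)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("separation detected: fitted probabilities of 0 or 1",
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged || any(abs(stats::coef(fit)) > 30)) {
    stop("logistic fit diverged (possible separation)", call. = FALSE)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  slope_idx <- -1L
  or <- exp(beta[slope_idx])
  or_ci <- cbind(low = exp(beta[slope_idx] - z * se[slope_idx]),
                 high = exp(beta[slope_idx] + z * se[slope_idx]))
  rownames(or_ci) <- names(or) <- colnames(x)
  list(coefficients = beta, se = se, or = or, or_ci = or_ci, n = n,
       converged = fit$converged)
}

#' @noRd
default_grids <- function() {
  list(age = list(direction = "ge", grid = c(65, 70, 75, 80, 85)),
       max_ais = list(direction = "ge", grid = c(3, 4, 5)),
       asa = list(direction = "ge", grid = c(2, 3)),
       gcs = list(direction = "le", grid = c(8, 12, 13)))
}

#' Screen candidate predictors for an additive mortality score
#'
#' Runs the development procedure on a filtered cohort: continuous
#' candidates (age, maximum AIS, ASA, GCS) are dichotomized by
#' [cutoff_search()] over their grids; inherently binary candidates
#' (pre-ICU transfusion, male sex, high-energy mechanism, systolic blood
#' pressure <= 90 mmHg) keep their fixed dichotomy. Each candidate's 2x2
#' mortality table and univariable odds ratio are computed; in
#' `multivariable` mode a joint logistic model over all dichotomized
#' candidates supplies the odds ratios instead. Records with missing
#' predictor values are excluded per variable and the evaluable counts are
#' reported.
#'
#' @param cohort A filtered cohort (or a data frame of records).
#' @param target_mortality Exposed-group mortality the cut-off search aims
#'   for (default 0.30).
#' @param mode `"univariable"` (default; the usual screening table) or
#'   `"multivariable"`.
#' @param grids Cut-off grids per continuous variable; see the default in
#'   the source.
#' @return Data frame with one row per candidate in the canonical order:
#'   `variable`, `cutoff`, `direction`, `n_exposed`, `n_unexposed`,
#'   `mortality_exposed`, `mortality_unexposed`, `or`, `ci_low`, `ci_high`,
#'   `n_dropped`.
#' @export
screen_candidates <- function(cohort, target_mortality = 0.30,
                              mode = c("univariable", "multivariable"),
                              grids = default_grids()) {
  mode <- match.arg(mode)
  records <- if (inherits(cohort, "gertality_cohort")) cohort$records
             else cohort
  fixed <- list(transfusion = list(direction = "true", cutoff = NA_real_),
                sex_male = list(direction = "true", cutoff = NA_real_),
                mechanism_high_energy = list(direction = "true",
                                             cutoff = NA_real_),
                sbp = list(direction = "le", cutoff = 90))
  rows <- list()
  criteria <- list()
  for (v in candidate_order) {
    if (v %in% names(grids)) {
      dir <- grids[[v]]$direction
      cut <- cutoff_search(records, v, grids[[v]]$grid, dir,
                           target_mortality)
      if (is.null(cut)) {
        rows[[v]] <- data.frame(variable = v, cutoff = NA_real_,
                                direction = dir, n_exposed = 0L,
                                n_unexposed = 0L,
                                mortality_exposed = NA_real_,
                                mortality_unexposed = NA_real_,
                                or = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_, n_dropped = NA_integer_,
                                stringsAsFactors = FALSE)
        next
      }
    } else {
      dir <- fixed[[v]]$direction
      cut <- fixed[[v]]$cutoff
    }
    cr <- make_criterion(v, dir, cut)
    criteria[[v]] <- cr
    tab <- contingency(records, cr)
    orr <- odds_ratio(tab)
    rows[[v]] <- data.frame(variable = v,
                            cutoff = if (dir == "true") NA_real_ else cut,
                            direction = dir,
                            n_exposed = orr$n_exposed,
                            n_unexposed = orr$n_unexposed,
                            mortality_exposed = orr$mortality_exposed,
                            mortality_unexposed = orr$mortality_unexposed,
                            or = orr$or, ci_low = orr$ci_low,
                            ci_high = orr$ci_high,
                            n_dropped = tab$n_dropped,
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows[candidate_order[candidate_order %in%
                                                  names(rows)]])
  rownames(report) <- NULL
  if (mode == "multivariable" && length(criteria)) {
    status <- vapply(criteria, function(cr) criterion_status(cr, records),
                     character(nrow(records)))
    design <- as.data.frame(status == "met")
    design[status == "unknown"] <- NA
    fit <- logistic_fit(design, records$died_in_hospital)
    idx <- match(names(criteria), report$variable)
    report$or[idx] <- unname(fit$or[names(criteria)])
    report$ci_low[idx] <- fit$or_ci[names(criteria), "low"]
    report$ci_high[idx] <- fit$or_ci[names(criteria), "high"]
  }
  attr(report, "mode") <- mode
  report
}

#' Select score criteria by odds-ratio threshold
#'
#' Keeps every candidate whose odds ratio exceeds the threshold (strictly)
#' and assembles the selected dichotomies into a one-point-per-criterion
#' score definition. Output order is the fixed canonical candidate order
#' (age, maximum AIS, transfusion, ASA, GCS, male sex, high-energy
#' mechanism, low systolic blood pressure), independent of input order.
#'
#' @param candidates Data frame with columns `variable`, `direction`,
#'   `cutoff`, `or` — typically a [screen_candidates()] report.
#' @param or_threshold Selection threshold on the odds ratio (default 2.0).
#' @param name Name for the resulting score.
#' @return A [score_definition()]; empty (with a warning) if no candidate
#'   passes.
#' @export
select_criteria <- function(candidates, or_threshold = 2.0,
                            name = "developed") {
  stopifnot(all(c("variable", "direction", "cutoff", "or") %in%
                  names(candidates)))
  keep <- !is.na(candidates$or) & candidates$or > or_threshold
  sel <- candidates[keep, , drop = FALSE]
  sel <- sel[order(match(sel$variable, candidate_order)), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no candidate exceeded the odds-ratio threshold; empty score")
    return(score_definition(name, list()))
  }
  crits <- lapply(seq_len(nrow(sel)), function(i) {
    make_criterion(sel$variable[i], sel$direction[i],
                   if (is.na(sel$cutoff[i])) NA_real_ else sel$cutoff[i])
  })
  score_definition(name, crits)
}

#' Full score-development run
#'
#' Convenience wrapper: screens all candidates on a filtered cohort and
#' selects those with odds ratio above the threshold.
#'
#' @inheritParams screen_candidates
#' @inheritParams select_criteria
#' @return List with `report` (the screening table) and `definition`
#'   (the selected [score_definition()]).
#' @export
develop_score <- function(cohort, target_mortality = 0.30,
                          or_threshold = 2.0,
                          mode = c("univariable", "multivariable"),
                          name = "developed") {
  report <- screen_candidates(cohort, target_mortality, mode)
  list(report = report,
       definition = select_criteria(report, or_threshold, name))
}

#' Published screening table from the original GERtality development cohort
#'
#' Subgroup sizes, mortality rates and univariable odds ratios reported for
#' the five selected predictors in the registry cohort (n = 58,055 European
#' geriatric trauma patients) on which the GERtality score was developed.
#' Useful as a reference fixture: rebuilding each 2x2 table from the
#' subgroup sizes and rounded mortality rates reproduces the published odds
#' ratios to within the rounding of the rates.
#'
#' @return Data frame with one row per selected predictor: `variable`,
#'   `cutoff`, `direction`, `n_exposed`, `n_unexposed`,
#'   `mortality_exposed`, `mortality_unexposed` (proportions, as published
#'   to one decimal percent), `or`, `ci_low`, `ci_high`.
#' @export
gertality_development_reference <- function() {
  data.frame(
    variable = c("age", "max_ais", "transfusion", "asa", "gcs"),
    cutoff = c(80, 4, NA, 3, 13),
    direction = c("ge", "ge", "true", "ge", "le"),
    n_exposed = c(21810L, 25924L, 4813L, 20235L, 22559L),
    n_unexposed = c(36245L, 32131L, 53242L, 28269L, 32719L),
    mortality_exposed = c(0.315, 0.387, 0.434, 0.291, 0.422),
    mortality_unexposed = c(0.168, 0.092, 0.204, 0.164, 0.088),
    or = c(2.27, 6.25, 2.99, 2.09, 7.61),
    ci_low = c(2.18, 5.97, 2.81, 2.00, 7.27),
    ci_high = c(2.36, 6.54, 3.17, 2.18, 7.89),
    stringsAsFactors = FALSE)
}
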