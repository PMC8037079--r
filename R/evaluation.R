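# Evaluation: mortality-by-score tables and ROC/AUC score comparison.

#' ROC analysis of a mortality score
#'
#' Computes the area under the ROC curve by the Mann-Whitney statistic with
#' ties counted one half:
#' `AUC = (#(pos > neg) + 0.5 * #(pos = neg)) / (n_pos * n_neg)`,
#' evaluated in O(n log n) via midranks. ROC points are taken at a threshold
#' for every distinct score value (orientation: higher score predicts
#' death; an anti-discriminating score yields AUC < 0.5 and is not
#' auto-flipped). The confidence interval uses DeLong's placement-value
#' variance estimate by default, or a stratified bootstrap.
#'
#' @param scores Numeric score vector.
#' @param outcomes Logical (or 0/1) vector; `TRUE` = died.
#' @param score_name Label carried into the result.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param boot_b Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return Object of class `roc_result`: `score_name`, `auc`, `ci_low`,
#'   `ci_high`, `se`, `roc_points` (data frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1), both coordinates non-decreasing), `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
roc_auc <- function(scores, outcomes, score_name = "score",
                    ci_method = c("delong", "bootstrap"),
                    conf_level = 0.95, boot_b = 2000) {
  ci_method <- match.arg(ci_method)
  outcomes <- as.logical(outcomes)
  keep <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[keep]; outcomes <- outcomes[keep]
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos < 1L || n_neg < 1L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  auc <- mw_auc(scores, outcomes)

  # placement values (DeLong): per-case probability of outranking the
  # opposite class, computable from combined and within-class midranks
  r_all <- rank(scores)
  v10 <- (r_all[outcomes] - rank(scores[outcomes])) / n_neg
  v01 <- 1 - (r_all[!outcomes] - rank(scores[!outcomes])) / n_pos
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    se <- sqrt(stats::var(v10) / n_pos + stats::var(v01) / n_neg)
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  } else {
    pos <- scores[outcomes]; neg <- scores[!outcomes]
    reps <- vapply(seq_len(boot_b), function(i) {
      mw_auc(c(sample(pos, n_pos, replace = TRUE),
               sample(neg, n_neg, replace = TRUE)),
             rep(c(TRUE, FALSE), c(n_pos, n_neg)))
    }, numeric(1))
    se <- stats::sd(reps)
    ci <- unname(stats::quantile(reps, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
  }

  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(scores[outcomes] >= t),
                numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!outcomes] >= t),
                numeric(1))
  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))

  structure(list(score_name = score_name, auc = auc,
                 ci_low = ci[1], ci_high = ci[2], se = se,
                 ci_method = ci_method, conf_level = conf_level,
                 roc_points = roc_points, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @noRd
mw_auc <- function(scores, outcomes) {
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  r <- rank(scores)
  (sum(r[outcomes]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC '%s': AUC %.3f (%.0f%% CI %.3f-%.3f, %s), %d deaths / %d survivors\n",
              x$score_name, x$auc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates the ROC polygon of a [roc_auc()] result. With midrank tie
#' handling this equals the Mann-Whitney AUC exactly, which makes it a
#' useful internal consistency check.
#'
#' @param roc A `roc_result`.
#' @return The trapezoidal area as a single number.
#' @export
auc_trapezoid <- function(roc) {
  p <- roc$roc_points
  sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
}

#' Observed mortality by score level
#'
#' Tabulates in-hospital mortality for each attainable score level (0 up to
#' `max_level`), with an exact binomial (Clopper-Pearson) confidence
#' interval per level. Records with a missing score are excluded from the
#' table and counted in the `n_missing` attribute.
#'
#' @param scored Data frame as returned by [score_cohort()] (or any data
#'   frame with the score and outcome columns).
#' @param score_col Name of the score column (default `"gertality"`).
#' @param outcome_col Name of the logical outcome column.
#' @param max_level Highest attainable score level (default 5).
#' @param conf_level Confidence level for the binomial interval.
#' @return Data frame with one row per level: `score`, `n`, `deaths`,
#'   `mortality`, `ci_low`, `ci_high`; levels with no patients have `n = 0`
#'   and missing rates. Row counts conserve the number of scored records.
#' @export
mortality_by_score <- function(scored, score_col = "gertality",
                               outcome_col = "died_in_hospital",
                               max_level = 5L, conf_level = 0.95) {
  s <- scored[[score_col]]; y <- as.logical(scored[[outcome_col]])
  n_missing <- sum(is.na(s))
  keep <- !is.na(s)
  s <- s[keep]; y <- y[keep]
  if (length(s) && (any(s < 0) || any(s > max_level))) {
    stop(sprintf("scores must lie in [0, %d]", max_level), call. = FALSE)
  }
  levels <- 0:max_level
  rows <- lapply(levels, function(l) {
    idx <- s == l
    n <- sum(idx); deaths <- sum(y[idx])
    if (n > 0) {
      ci <- stats::binom.test(deaths, n, conf.level = conf_level)$conf.int
      data.frame(score = l, n = n, deaths = deaths, mortality = deaths / n,
                 ci_low = ci[1], ci_high = ci[2])
    } else {
      data.frame(score = l, n = 0L, deaths = 0L, mortality = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "n_missing") <- n_missing
  out
}

#' Compare scores by AUC on a common record subset
#'
#' Scores the cohort, restricts to the records on which every requested
#' score is evaluable (so all AUCs are computed on the identical subset),
#' runs [roc_auc()] for each score, and orders the results by AUC
#' descending.
#'
#' @param cohort A filtered cohort.
#' @param score_names Character vector of at least two of `"gertality"`,
#'   `"gtos"`, `"max_ais"`, `"iss"`, `"age"`.
#' @param missing_policy Passed to [score_cohort()] for the GERtality score.
#' @param ci_method Passed to [roc_auc()].
#' @return Data frame (`score`, `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`) ordered by AUC descending, with the full `roc_result` objects
#'   in the `"roc"` attribute.
#' @export
compare_scores <- function(cohort,
                           score_names = c("gertality", "gtos", "max_ais",
                                           "iss", "age"),
                           missing_policy = c("zero_points",
                                              "propagate_missing"),
                           ci_method = c("delong", "bootstrap")) {
  available <- c("gertality", "gtos", "max_ais", "iss", "age")
  stopifnot(all(score_names %in% available), length(score_names) >= 2)
  scored <- score_cohort(cohort, missing_policy)
  mat <- scored[, score_names, drop = FALSE]
  keep <- stats::complete.cases(mat)
  if (!any(keep)) stop("no record has all requested scores evaluable",
                       call. = FALSE)
  mat <- mat[keep, , drop = FALSE]
  y <- scored$died_in_hospital[keep]
  rocs <- lapply(score_names, function(nm) {
    roc_auc(mat[[nm]], y, score_name = nm, ci_method = ci_method)
  })
  names(rocs) <- score_names
  out <- data.frame(score = score_names,
                    auc = vapply(rocs, `[[`, numeric(1), "auc"),
                    ci_low = vapply(rocs, `[[`, numeric(1), "ci_low"),
                    ci_high = vapply(rocs, `[[`, numeric(1), "ci_high"),
                    n_pos = vapply(rocs, `[[`, integer(1), "n_pos"),
                    n_neg = vapply(rocs, `[[`, integer(1), "n_neg"),
                    stringsAsFactors = FALSE)
  ord <- order(out$auc, decreasing = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "roc") <- rocs[ord]
  out
}
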