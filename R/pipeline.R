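# Pipeline wiring: simulate -> filter -> develop -> score -> evaluate,
# with a run manifest for provenance.

#' @noRd
config_hash <- function(x) {
  # tiny rolling content hash for run manifests
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
write_manifest <- function(out_dir, command, config, seed, outputs) {
  manifest <- list(command = command,
                   config_hash = config_hash(config),
                   seed = seed,
                   outputs = outputs,
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   package_version =
                     as.character(utils::packageVersion("gertality")))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' @noRd
definition_as_df <- function(definition) {
  if (!length(definition$criteria)) {
    return(data.frame(criterion = character(), variable = character(),
                      direction = character(), cutoff = numeric()))
  }
  data.frame(
    criterion = vapply(definition$criteria, `[[`, character(1), "name"),
    variable = vapply(definition$criteria, `[[`, character(1), "variable"),
    direction = vapply(definition$criteria, `[[`, character(1), "direction"),
    cutoff = vapply(definition$criteria, `[[`, numeric(1), "cutoff"),
    stringsAsFactors = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes one stage or the full chain on a synthetic cohort:
#' `simulate` (generate a cohort CSV), `filter` (inclusion/exclusion),
#' `develop` (screening report and selected score definition), `score`
#' (per-patient GERtality/GTOS/ISS/max-AIS columns), `evaluate`
#' (mortality-by-score and AUC comparison tables), or `all`. Every run
#' writes a `manifest.json` (command, config hash, seed, outputs, package
#' version) next to its outputs. Output bytes are identical across runs
#' with the same config and seed, apart from the manifest timestamp.
#'
#' @param command One of `"simulate"`, `"filter"`, `"develop"`, `"score"`,
#'   `"evaluate"`, `"all"`.
#' @param out_dir Output directory (created if absent).
#' @param input Input CSV path for single-stage commands that consume a
#'   cohort (`filter`, `develop`, `score`) or a scored cohort (`evaluate`);
#'   ignored by `simulate` and `all`.
#' @param n,seed Synthetic cohort size and seed (for `simulate`/`all`).
#' @param missing_policy `"zero_points"` or `"propagate_missing"`.
#' @param or_threshold,target_mortality,mode Development parameters, see
#'   [develop_score()].
#' @param generator A [generator_config()] overriding `n`/`seed` if given.
#' @return Invisibly, a named character vector of the files written
#'   (including the manifest).
#' @export
run_pipeline <- function(command = c("all", "simulate", "filter", "develop",
                                     "score", "evaluate"),
                         out_dir, input = NULL, n = 10000L, seed = 1L,
                         missing_policy = c("zero_points",
                                            "propagate_missing"),
                         or_threshold = 2.0, target_mortality = 0.30,
                         mode = c("univariable", "multivariable"),
                         generator = NULL) {
  command <- match.arg(command)
  missing_policy <- match.arg(missing_policy)
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- generator %||% generator_config(n = n, seed = seed)
  outputs <- character()
  out <- function(name) file.path(out_dir, name)

  cohort <- NULL
  if (command %in% c("simulate", "all")) {
    cohort <- generate_cohort(config)
    write_cohort(cohort, out("cohort.csv"))
    outputs["cohort"] <- out("cohort.csv")
  } else if (command != "evaluate") {
    if (is.null(input)) stop("'input' is required for this command",
                             call. = FALSE)
    cohort <- read_cohort(input)
  }

  if (command %in% c("filter", "all")) {
    cohort <- apply_inclusion_filter(cohort)
    write_cohort(cohort, out("filtered.csv"),
                 exclusion_path = out("exclusion_log.csv"))
    outputs["filtered"] <- out("filtered.csv")
    outputs["exclusion_log"] <- out("exclusion_log.csv")
  }

  if (command %in% c("develop", "all")) {
    if (command == "develop") cohort <- apply_inclusion_filter(cohort)
    dev <- develop_score(cohort, target_mortality, or_threshold, mode)
    report <- dev$report
    report$selected <- !is.na(report$or) & report$or > or_threshold
    utils::write.csv(report, out("screening_report.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(definition_as_df(dev$definition),
                     out("score_definition.csv"), row.names = FALSE)
    outputs["screening_report"] <- out("screening_report.csv")
    outputs["score_definition"] <- out("score_definition.csv")
  }

  scored <- NULL
  if (command %in% c("score", "all")) {
    if (command == "score") cohort <- apply_inclusion_filter(cohort)
    scored <- score_cohort(cohort, missing_policy)
    utils::write.csv(scored, out("scored.csv"), row.names = FALSE, na = "")
    outputs["scored"] <- out("scored.csv")
  }

  if (command %in% c("evaluate", "all")) {
    if (command == "evaluate") {
      if (is.null(input)) stop("'input' is required for this command",
                               call. = FALSE)
      scored <- utils::read.csv(input)
      scored$died_in_hospital <- parse_boolean(scored$died_in_hospital)
    }
    mbs <- mortality_by_score(scored)
    utils::write.csv(mbs, out("mortality_by_score.csv"), row.names = FALSE,
                     na = "")
    comp <- if (command == "evaluate") {
      # scored CSV already carries all score columns
      scores <- c("gertality", "gtos", "max_ais", "iss", "age")
      keep <- stats::complete.cases(scored[, scores])
      res <- lapply(scores, function(nm) {
        roc_auc(scored[[nm]][keep], scored$died_in_hospital[keep],
                score_name = nm)
      })
      df <- data.frame(score = scores,
                       auc = vapply(res, `[[`, numeric(1), "auc"),
                       ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
                       ci_high = vapply(res, `[[`, numeric(1), "ci_high"))
      df[order(df$auc, decreasing = TRUE), ]
    } else {
      compare_scores(cohort, missing_policy = missing_policy)
    }
    utils::write.csv(comp, out("auc_comparison.csv"), row.names = FALSE,
                     na = "")
    outputs["mortality_by_score"] <- out("mortality_by_score.csv")
    outputs["auc_comparison"] <- out("auc_comparison.csv")
  }

  outputs["manifest"] <- write_manifest(out_dir, command, config,
                                        config$seed, as.list(outputs))
  invisible(outputs)
}
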