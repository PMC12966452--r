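# End-to-end pipeline orchestration: cohort in (file or generator), then
# exclusion, optional matching, split, repeated forests, importance
# inference, co-occurrence and the questionnaire comparison, with every
# artifact written as CSV/JSON and every seed recorded in a manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the analysis' reference settings: master seed 1974,
#' an 80/20 train/test split, 1000 repetitions and alpha = 0.05.
#'
#' @param cohort a cohort data frame, a path to a cohort CSV, or a
#'   [synthetic_config()] to generate one.
#' @param results_dir directory the artifacts are written into (created if
#'   needed).
#' @param master_seed seed from which every stage's seed derives.
#' @param train_fraction train share of the split.
#' @param n_repetitions repetitions for the real and null forest runs.
#' @param alpha significance level for importance inference.
#' @param hyperparameters `"fixed"` (use `hp`) or `"tuned"` (grid search on
#'   the training rows).
#' @param hp the fixed hyperparameters; default [rf_hyperparams()] when
#'   `sample_mode = "full"`, [matched_hyperparams()] when `"matched"`.
#' @param sample_mode analyse the `"full"` cohort or the age/gender
#'   `"matched"` subsample.
#' @param include_aq run the AQ threshold sweep and combined model.
#' @param match_target_size optional number of matched pairs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = synthetic_config(),
                            results_dir = "results",
                            master_seed = 1974L,
                            train_fraction = 0.8,
                            n_repetitions = 1000L,
                            alpha = 0.05,
                            hyperparameters = c("fixed", "tuned"),
                            hp = NULL,
                            sample_mode = c("full", "matched"),
                            include_aq = TRUE,
                            match_target_size = NULL) {
  sample_mode <- match.arg(sample_mode)
  hyperparameters <- match.arg(hyperparameters)
  if (is.null(hp)) {
    hp <- if (sample_mode == "matched") matched_hyperparams() else rf_hyperparams()
  }
  stopifnot(inherits(hp, "rf_hyperparams"),
            train_fraction > 0, train_fraction < 1,
            n_repetitions >= 1, alpha >= 0, alpha <= 1)
  structure(list(
    cohort = cohort,
    results_dir = results_dir,
    master_seed = as.integer(master_seed),
    train_fraction = train_fraction,
    n_repetitions = as.integer(n_repetitions),
    alpha = alpha,
    hyperparameters = hyperparameters,
    hp = hp,
    sample_mode = sample_mode,
    include_aq = include_aq,
    match_target_size = match_target_size
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Field names mirror [pipeline_config()]; `hp` may be given as a mapping
#' of the five hyperparameter fields, and `cohort` as a file path or a
#' mapping of [synthetic_config()] fields.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$hp)) args$hp <- do.call(rf_hyperparams, raw$hp)
  if (is.list(raw$cohort)) args$cohort <- do.call(synthetic_config, raw$cohort)
  do.call(pipeline_config, args)
}

resolve_cohort <- function(cohort) {
  if (inherits(cohort, "synthetic_config")) return(generate_cohort(cohort))
  if (is.character(cohort)) return(read_cohort(cohort))
  if (inherits(cohort, "cohort") || is.data.frame(cohort)) return(cohort)
  stop("cohort must be a data frame, a CSV path, or a synthetic_config",
       call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: resolve the cohort, exclude incomplete records, optionally build
#' the age/gender-matched subsample, split, run the repeated real-label and
#' randomized-label forests, importance inference, co-occurrence contrast,
#' and (optionally) the AQ sweep and combined model.  Identical
#' configurations produce byte-identical artifacts; all stage seeds derive
#' from `master_seed`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths (`manifest$artifacts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$results_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$results_dir, name)
  artifacts <- character(0)
  note <- function(path) {
    artifacts <<- c(artifacts, path)
    path
  }
  # partial failure: keep whatever was written and record the error
  on.exit({
    if (!is.null(pipeline_error)) {
      jsonlite::write_json(
        list(error = pipeline_error, artifacts = basename(artifacts)),
        art("error_manifest.json"), auto_unbox = TRUE)
    }
  })
  pipeline_error <- NULL
  run_stages <- function() {
  seed <- config$master_seed

  records <- resolve_cohort(config$cohort)
  records <- exclude_incomplete(records)
  if (nrow(records) < 4) stop("too few complete records", call. = FALSE)
  if (config$sample_mode == "matched") {
    records <- match_age_gender(records, seed = seed + 1L,
                                target_size = config$match_target_size)
  }

  summary_tab <- cohort_summary(records)
  utils::write.csv(summary_tab, note(art("cohort_summary.csv")),
                   row.names = FALSE)

  fm <- build_feature_matrix(records)
  split <- split_train_test(fm, train_fraction = config$train_fraction,
                            seed = seed)
  write_split(split, note(art("split_spec.json")))

  hp <- config$hp
  if (config$hyperparameters == "tuned") {
    message("tuning hyperparameters by 3-fold grid search")
    hp <- tune_hyperparameters(fm, rows = split$train_indices,
                               seed = seed + 2L)
  }

  message("fitting ", config$n_repetitions, " real-label forests")
  real <- repeat_fit(fm, split, hp, n_repetitions = config$n_repetitions,
                     seed = seed + 10L)
  message("fitting ", config$n_repetitions, " randomized-label forests")
  null <- null_forest_importances(fm, split, hp,
                                  n_repetitions = config$n_repetitions,
                                  seed = seed + 20L)
  utils::write.csv(
    rbind(cbind(model = "real", real$metrics),
          cbind(model = "null", null$metrics)),
    note(art("repetition_metrics.csv")), row.names = FALSE)

  best <- select_best(real)
  best_report <- list(
    repetition = best,
    metrics = as.list(real$metrics[best, ]),
    hyperparams = unclass(hp),
    n_repetitions = config$n_repetitions
  )
  jsonlite::write_json(best_report, note(art("best_model.json")),
                       auto_unbox = TRUE, digits = NA)

  inference <- test_significance(real, null, alpha = config$alpha)
  utils::write.csv(as.data.frame(inference),
                   note(art("importance_inference.csv")), row.names = FALSE)
  message(sum(inference$significant), " of ", nrow(inference),
          " features significant at Bonferroni-corrected alpha ",
          config$alpha)

  contrast <- cooccurrence_null_contrast(real, null)
  write_cooccurrence(contrast$real, note(art("cooccurrence.csv")))
  write_cooccurrence(contrast$null, note(art("cooccurrence_null.csv")))

  aq_result <- NULL
  if (config$include_aq) {
    message("AQ threshold sweep and combined model")
    aq_result <- compare_sources(records, hp, split,
                                 n_repetitions = config$n_repetitions,
                                 seed = seed + 10L)
    utils::write.csv(as.data.frame(aq_result$aq_sweep),
                     note(art("aq_sweep.csv")), row.names = FALSE)
    jsonlite::write_json(
      list(comparison = aq_result$comparison,
           aq_best_threshold = aq_result$aq_best_threshold),
      note(art("comparison.json")), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    master_seed = config$master_seed,
    stage_seeds = list(split = seed, matching = seed + 1L,
                       tuning = seed + 2L, real_forests = seed + 10L,
                       null_forests = seed + 20L),
    train_fraction = config$train_fraction,
    n_repetitions = config$n_repetitions,
    alpha = config$alpha,
    sample_mode = config$sample_mode,
    include_aq = config$include_aq,
    hyperparams = unclass(hp),
    n_records = nrow(records),
    n_features = length(fm$feature_names),
    artifacts = basename(artifacts)
  )
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(records = records, feature_matrix = fm, split = split,
       hyperparams = hp, real = real, null = null,
       best_index = best, inference = inference,
       cooccurrence = contrast, aq = aq_result,
       manifest = manifest,
       artifact_paths = c(artifacts, art("manifest.json")))
  }
  out <- withCallingHandlers(run_stages(), error = function(e) {
    pipeline_error <<- conditionMessage(e)
  })
  invisible(out)
}
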