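#' Read food-record summary tables
#'
#' Delimited text, one participant per row: `participant_id`, food-group
#' gram columns and nutrient columns.  All numeric values must be finite
#' and nonnegative.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return A tibble.
#' @export
read_food_records <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  if (!"participant_id" %in% names(x)) {
    .fiq_stop(sprintf("'%s': no participant_id column", path), "fiq_schema_error")
  }
  num <- x[, setdiff(names(x), c("participant_id", "zero_energy")), drop = FALSE]
  bad <- names(num)[vapply(num, function(v) !is.numeric(v) || any(!is.finite(v) | v < 0),
                           logical(1))]
  if (length(bad) > 0) {
    .fiq_stop(paste0(path, ": non-numeric, missing or negative values in: ",
                     paste(bad, collapse = ", ")), "fiq_schema_error")
  }
  x
}

#' Pipeline configuration and stages
#'
#' The analysis pipeline is driven by a small YAML (or list)
#' configuration: paths to the codebook, composition table, input tables
#' and output directory, plus statistical options.  Each stage reads its
#' inputs, never mutates them, writes into `output_dir` only, and is
#' deterministic given fixed inputs and seed.  A thin command-line wrapper
#' over these stages ships at `system.file("cli", "fiq.R", package =
#' "fiq16")` with subcommands `simulate`, `estimate`, `validate`,
#' `fit-models` and `score`.
#'
#' Recognised configuration fields: `output_dir`; `codebook`,
#' `composition` (paths, or omitted for the packaged defaults); `delim`;
#' `seed`, `n`, `n_male` (simulation); `responses`, `records` (input
#' paths); `kappa_scheme`; `fit` (a list of model recipes, each with
#' `nutrient`, `target`, `items`, optional `log`, `units`, `init`);
#' `models` (paths of scoring-model files, or `"published"` for the
#' packaged fat model).
#'
#' @param config A list or path to a YAML configuration file.
#' @return Each stage invisibly returns the paths it wrote.
#' @name fiq_pipeline
NULL

read_fiq_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(output_dir = ".", delim = ",", seed = 1L, n = 77,
                   n_male = NULL, kappa_scheme = "linear")
  modifyList(defaults, config)
}

config_env <- function(cfg) {
  list(
    codebook = if (is.null(cfg$codebook)) fiq_codebook() else fiq_codebook(cfg$codebook),
    composition = if (is.null(cfg$composition)) read_composition() else read_composition(cfg$composition)
  )
}

out_path <- function(cfg, name) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  file.path(cfg$output_dir, name)
}

#' @rdname fiq_pipeline
#' @export
fiq_stage_simulate <- function(config) {
  cfg <- read_fiq_config(config)
  env <- config_env(cfg)
  cohort <- generate_cohort(
    cohort_spec(n = cfg$n, n_male = cfg$n_male, seed = cfg$seed),
    codebook = env$codebook, composition = env$composition
  )
  paths <- c(out_path(cfg, "responses.csv"), out_path(cfg, "food_records.csv"))
  write_responses(cohort$responses, paths[1], delim = cfg$delim)
  readr::write_delim(cohort$records, paths[2], delim = cfg$delim)
  invisible(paths)
}

#' @rdname fiq_pipeline
#' @export
fiq_stage_estimate <- function(config) {
  cfg <- read_fiq_config(config)
  env <- config_env(cfg)
  responses <- read_responses(cfg$responses, env$codebook, delim = cfg$delim,
                              missing_as_zero = isTRUE(cfg$missing_as_zero))
  est <- estimate_nutrients(responses, env$codebook,
                            estimation_config(env$composition))
  est <- dplyr::bind_cols(tibble(participant_id = responses$participant_id), est)
  p <- out_path(cfg, "questionnaire_nutrients.csv")
  readr::write_delim(est, p, delim = cfg$delim)
  invisible(p)
}

#' @rdname fiq_pipeline
#' @export
fiq_stage_validate <- function(config) {
  cfg <- read_fiq_config(config)
  env <- config_env(cfg)
  responses <- read_responses(cfg$responses, env$codebook, delim = cfg$delim)
  records <- read_food_records(cfg$records, delim = cfg$delim)
  est <- estimate_nutrients(responses, env$codebook, estimation_config(env$composition))
  est$participant_id <- responses$participant_id
  report <- fiq_validate(
    estimates = est, references = records,
    frequencies = fiq_food_group_frequencies(responses, env$codebook),
    kappa_scheme = cfg$kappa_scheme
  )
  invisible(write_validation_report(report, cfg$output_dir, delim = cfg$delim))
}

#' @rdname fiq_pipeline
#' @export
fiq_stage_fit_models <- function(config) {
  cfg <- read_fiq_config(config)
  env <- config_env(cfg)
  if (is.null(cfg$fit)) .fiq_stop("config has no `fit` recipes", "fiq_config_error")
  responses <- read_responses(cfg$responses, env$codebook, delim = cfg$delim)
  records <- read_food_records(cfg$records, delim = cfg$delim)
  items_tbl <- encode_scoring_items(responses, env$codebook)
  records <- records[match(items_tbl$participant_id, records$participant_id), ]
  paths <- character()
  for (recipe in cfg$fit) {
    d <- dplyr::bind_cols(items_tbl,
                          records[, recipe$target, drop = FALSE])
    init <- if (!is.null(recipe$init)) unlist(recipe$init)
    model <- fit_scoring_model(
      d, target = recipe$target, items = unlist(recipe$items),
      init = init, log_flag = isTRUE(recipe$log),
      nutrient = recipe$nutrient %||% recipe$target,
      units = recipe$units %||% ""
    )
    p_model <- out_path(cfg, paste0("model_", model$nutrient, ".yaml"))
    write_scoring_model(model, p_model)
    p_resid <- out_path(cfg, paste0("residuals_", model$nutrient, ".csv"))
    readr::write_delim(residual_diagnostics(model, d, recipe$target), p_resid,
                       delim = cfg$delim)
    paths <- c(paths, p_model, p_resid)
  }
  invisible(paths)
}

#' @rdname fiq_pipeline
#' @export
fiq_stage_score <- function(config) {
  cfg <- read_fiq_config(config)
  env <- config_env(cfg)
  responses <- read_responses(cfg$responses, env$codebook, delim = cfg$delim)
  models <- if (is.null(cfg$models) || identical(cfg$models, "published")) {
    list(published_fat_model())
  } else {
    lapply(cfg$models, read_scoring_model)
  }
  scores <- score_cohort(models, responses, env$codebook)
  p <- out_path(cfg, "patient_scores.csv")
  readr::write_delim(scores, p, delim = cfg$delim)
  invisible(p)
}
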