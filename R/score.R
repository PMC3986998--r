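#' The published fat-intake scoring model
#'
#' The fat (E%) scoring model printed with the questionnaire's scoring
#' table: prediction `36.66 + 0.45 x SC`, where the sum score SC adds
#' sausage dishes per week (x1), fruit and berry portions per day (x-12),
#' cheese slices per day (x1), frankfurter slices per day (x3), -5 points
#' for men, and a butter-used-for-cooking term whose "no" branch
#' contributes 0 points.  The numeric coefficient of the "yes" branch is
#' printed only inside the scoring-table figure and is not recoverable from
#' the text, so it is stored as `NA`: the model scores any participant who
#' does not use butter for cooking, and raises an informative error
#' otherwise.
#'
#' The published worked example — a man reporting 2 sausage dishes/week, no
#' butter in cooking, 1 fruit portion/day, 6 cheese slices/day and no
#' frankfurters — gives `SC = 2 + 0 - 12 + 6 + 0 - 5 = -9` and an
#' estimated fat intake of `36.66 + (-9 x 0.45) = 32.6 E%`.
#'
#' @return An `fiq_model` for fat in E%.
#' @export
#' @examples
#' score_cohort(published_fat_model(), example_participant())
published_fat_model <- function() {
  new_fiq_model(
    nutrient = "fat", units = "E%",
    multipliers = c(dishes_sausage = 1, butter_in_cooking = NA,
                    fruit_per_day = -12, cheese_slices = 1,
                    coldcut_frankfurter_slices = 3, male = -5),
    intercept = 36.66, slope = 0.45, log_flag = FALSE,
    source = "published"
  )
}

#' Score one questionnaire response with a scoring model
#'
#' Builds the model's sum score from the encoded answers and evaluates the
#' prediction: `intercept + slope x SC` for linear models, or
#' `bias_factor x exp(intercept + slope x SC)` for log-scale models.
#' Negative predictions are clamped to zero with a warning (intakes cannot
#' be negative).
#'
#' @param model An `fiq_model`.
#' @param response A one-row response table (or a row of encoded items from
#'   [encode_scoring_items()]).
#' @inheritParams validate_responses
#' @return A one-row tibble: `participant_id`, `nutrient`, `sum_score`,
#'   `estimate`, `units`.
#' @export
#' @examples
#' score_response(published_fat_model(), example_participant())
score_response <- function(model, response, codebook = fiq_codebook()) {
  items <- if (all(names(model$multipliers) %in% names(response))) {
    as_tibble(response)
  } else {
    encode_scoring_items(response, codebook)
  }
  missing_items <- setdiff(names(model$multipliers), names(items))
  if (length(missing_items) > 0) {
    .fiq_stop(paste0("response lacks model item(s): ",
                     paste(missing_items, collapse = ", ")), "fiq_coding_error")
  }
  sc <- build_sum_score(items, model$multipliers)
  est <- predict_from_score(model, sc)
  tibble(
    participant_id = if ("participant_id" %in% names(items)) items$participant_id else NA_character_,
    nutrient = model$nutrient, sum_score = sc, estimate = est, units = model$units
  )
}

predict_from_score <- function(model, sc, clamp = TRUE) {
  pred <- if (model$log_flag) {
    model$bias_factor * exp(model$intercept + model$slope * sc)
  } else {
    model$intercept + model$slope * sc
  }
  if (clamp && any(pred < 0)) {
    warn(sprintf("%d negative %s prediction(s) clamped to 0", sum(pred < 0), model$nutrient))
    pred <- pmax(pred, 0)
  }
  pred
}

#' Score a cohort with a set of models
#'
#' Applies each scoring model to every participant: one row per
#' participant, one `sum_score` / `estimate` column pair per nutrient.
#' A participant whose answers cannot be scored under some model (e.g. a
#' nonzero value on an undetermined-coefficient item) is flagged rather
#' than failing the whole cohort: the affected cells are `NA` and the
#' `flag` column records the error.
#'
#' @param models An `fiq_model` or a list of them.
#' @param responses A response table.
#' @inheritParams validate_responses
#' @return A tibble with one row per participant.
#' @export
#' @examples
#' score_cohort(published_fat_model(), example_participant())
score_cohort <- function(models, responses, codebook = fiq_codebook()) {
  if (inherits(models, "fiq_model")) models <- list(models)
  responses <- as_tibble(responses)
  if (nrow(responses) == 0) {
    return(tibble(participant_id = character(), flag = character()))
  }
  items <- encode_scoring_items(responses, codebook)
  out <- tibble(participant_id = items$participant_id, flag = NA_character_)
  for (model in models) {
    sc_col <- paste0(model$nutrient, "_sum_score")
    est_col <- paste0(model$nutrient, "_estimate")
    out[[sc_col]] <- NA_real_
    out[[est_col]] <- NA_real_
    for (i in seq_len(nrow(items))) {
      res <- tryCatch(
        {
          sc <- build_sum_score(items[i, , drop = FALSE], model$multipliers)
          c(sc, predict_from_score(model, sc))
        },
        fiq_error = function(e) {
          out$flag[i] <<- paste0(model$nutrient, ": ", conditionMessage(e))
          c(NA_real_, NA_real_)
        }
      )
      out[[sc_col]][i] <- res[1]
      out[[est_col]][i] <- res[2]
    }
  }
  out
}
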