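#' Questionnaire response tables
#'
#' A response table holds one participant per row: an id, sex, one
#' categorical column per frequency/choice item and one nonnegative numeric
#' column per open-item field, as defined by the codebook.
#' [validate_responses()] enforces completeness (missing answers are an
#' error by default — the screener has no missing-data protocol), membership
#' of every categorical answer in the codebook's allowed set, and
#' nonnegative finite counts.
#'
#' @param responses A data frame of questionnaire answers.
#' @param codebook An [fiq_codebook()] object.
#' @param missing_as_zero If `TRUE`, missing numeric answers are replaced by
#'   zero (with a warning) instead of raising an error.
#' @return `validate_responses()` returns the validated tibble, invisibly
#'   coerced with columns in canonical order.
#' @export
validate_responses <- function(responses, codebook = fiq_codebook(),
                               missing_as_zero = FALSE) {
  responses <- as_tibble(responses)
  cols <- response_columns(codebook)
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols) > 0) {
    .fiq_stop(paste0("response table lacks columns: ",
                     paste(missing_cols, collapse = ", ")), "fiq_schema_error")
  }
  if (anyDuplicated(responses$participant_id)) {
    .fiq_stop("duplicate participant_id", "fiq_schema_error")
  }
  bad_sex <- setdiff(unique(responses$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    .fiq_stop(paste0("invalid sex value: ", paste(bad_sex, collapse = ", ")),
              "fiq_coding_error")
  }
  # categorical items
  for (id in names(codebook$items)) {
    it <- codebook$items[[id]]
    if (it$type %in% c("frequency", "choice")) {
      allowed <- if (it$type == "frequency") it$categories$code else unlist(it$choices)
      vals <- responses[[it$column]]
      if (anyNA(vals)) {
        .fiq_stop(sprintf("item '%s' (%s): missing answer", id, it$column),
                  "fiq_missing_error")
      }
      bad <- setdiff(unique(vals), allowed)
      if (length(bad) > 0) {
        .fiq_stop(sprintf("item '%s' (%s): unknown answer '%s'",
                          id, it$column, paste(bad, collapse = ", ")),
                  "fiq_coding_error")
      }
    }
  }
  # numeric open fields
  num_cols <- codebook_field_map(codebook) %>% filter(.data$kind == "open") %>% pull("column")
  for (cl in num_cols) {
    v <- responses[[cl]]
    if (!is.numeric(v)) .fiq_stop(sprintf("column '%s' must be numeric", cl), "fiq_schema_error")
    if (anyNA(v)) {
      if (missing_as_zero) {
        warn(sprintf("column '%s': %d missing answers treated as zero", cl, sum(is.na(v))))
        v[is.na(v)] <- 0
        responses[[cl]] <- v
      } else {
        .fiq_stop(sprintf("column '%s': missing answer", cl), "fiq_missing_error")
      }
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      .fiq_stop(sprintf("column '%s': values must be finite and >= 0", cl), "fiq_coding_error")
    }
  }
  responses[, cols]
}

#' @rdname validate_responses
#' @export
response_columns <- function(codebook = fiq_codebook()) {
  fm <- codebook_field_map(codebook)
  c("participant_id", "sex", unname(choice_columns(codebook)), fm$column)
}

#' Read and write questionnaire response tables
#'
#' Delimited text with a header row, one participant per row, columns as in
#' [response_columns()]. The decimal separator is always `"."`.
#'
#' @param path File path.
#' @inheritParams validate_responses
#' @param delim Field delimiter (default comma).
#' @return `read_responses()` returns a validated tibble.
#' @export
read_responses <- function(path, codebook = fiq_codebook(), delim = ",",
                           missing_as_zero = FALSE) {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_responses(x, codebook, missing_as_zero = missing_as_zero)
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path, delim = ",") {
  readr::write_delim(responses, path, delim = delim)
  invisible(path)
}

#' The published worked-example participant
#'
#' A single-row response table encoding the male participant of the
#' published fat-score example: 2 sausage dishes per week, no butter used
#' for cooking, 1 portion of fruits and berries per day, 6 slices of cheese
#' per day, no frankfurters.  Items not exercised by the example are set to
#' neutral values (zero counts, `none`/`never` choices, lowest meal
#' category).  Scoring this participant with [published_fat_model()] gives
#' sum score -9 and an estimated fat intake of 32.6 E%.
#'
#' @param codebook An [fiq_codebook()] object.
#' @return A one-row validated response tibble.
#' @export
#' @examples
#' score_cohort(published_fat_model(), example_participant())
example_participant <- function(codebook = fiq_codebook()) {
  x <- tibble(
    participant_id = "worked-example", sex = "male",
    meals_per_day = "3-4", freq_fastfood = "never", freq_fruit = "1/day",
    freq_vegetable = "never", freq_sugar_rich = "never", freq_sweets = "never",
    cooking_fat_type = "vegetable_oil_or_margarine", cream_in_cooking = "never",
    spread_on_bread_type = "none", dressing_type = "none",
    dishes_fish = 0, dishes_sausage = 2, dishes_chicken = 0, dishes_meat = 0,
    dishes_vegetable = 0,
    milk_fat_free_dl = 0, milk_low_fat_dl = 0, milk_whole_dl = 0,
    cheese_low_fat_slices = 0, cheese_regular_slices = 6,
    coldcut_low_fat_slices = 0, coldcut_regular_slices = 0,
    coldcut_frankfurter_slices = 0,
    bread_rye_crisp_slices = 0, bread_multigrain_slices = 0, bread_white_slices = 0,
    cereal_porridge_dl = 0, cereal_flakes_dl = 0,
    bev_coffee_cups = 0, bev_tea_cups = 0, bev_soft_drink_glasses = 0,
    bev_sweetened_juice_glasses = 0, bev_fruit_juice_glasses = 0,
    bev_beer_bottles = 0, bev_wine_glasses = 0, bev_spirits_servings = 0
  )
  validate_responses(x, codebook)
}
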