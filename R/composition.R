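#' Food composition table
#'
#' One row per questionnaire food item: the gram weight of one reported
#' unit (a serving, slice, decilitre or glass) and nutrient densities per
#' 100 g.  The packaged table holds plausible fixture values for typical
#' Finnish foods — it is documentation-level stand-in data, not a copy of
#' any national composition database — and can be replaced by a file of the
#' same layout.
#'
#' Validity requires nonnegative densities, macronutrients
#' (fat + protein + carbohydrate + alcohol) summing to at most 100 g per
#' 100 g, sucrose no larger than carbohydrate and saturated fat no larger
#' than total fat.
#'
#' @param path Path to a delimited composition file, or `NULL` for the
#'   packaged fixture.
#' @param delim Field delimiter.
#' @return A validated tibble with class `fiq_composition`.
#' @export
#' @examples
#' comp <- read_composition()
#' comp[comp$item_id == "fruit", ]
read_composition <- function(path = NULL, delim = ",") {
  if (is.null(path)) {
    path <- system.file("extdata", "composition.csv", package = "fiq16")
  }
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_composition(x)
}

#' @rdname read_composition
#' @param x A data frame with the composition layout.
#' @export
validate_composition <- function(x) {
  x <- as_tibble(x)
  need <- c("item_id", "portion_g", "fat_g", "saturated_fat_g", "protein_g",
            "carbohydrate_g", "sucrose_g", "fibre_g", "alcohol_g",
            "vitamin_d_ug", "vitamin_c_mg", "calcium_mg", "iron_mg")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    .fiq_stop(paste0("composition table lacks columns: ",
                     paste(missing_cols, collapse = ", ")), "fiq_schema_error")
  }
  if (anyDuplicated(x$item_id)) .fiq_stop("duplicate item_id in composition table", "fiq_schema_error")
  num <- x[, setdiff(need, "item_id")]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) < 0)) {
    .fiq_stop("composition values must be finite and >= 0", "fiq_schema_error")
  }
  macro <- x$fat_g + x$protein_g + x$carbohydrate_g + x$alcohol_g
  bad <- x$item_id[macro > 100 | x$sucrose_g > x$carbohydrate_g | x$saturated_fat_g > x$fat_g]
  if (length(bad) > 0) {
    .fiq_stop(paste0("implausible composition for: ", paste(bad, collapse = ", ")),
              "fiq_schema_error")
  }
  class(x) <- c("fiq_composition", class(x))
  x
}

composition_lookup <- function(composition, item_id, context = "estimation") {
  idx <- match(item_id, composition$item_id)
  if (anyNA(idx)) {
    .fiq_stop(sprintf("%s: no composition entry for item '%s'", context,
                      paste(item_id[is.na(idx)], collapse = ", ")),
              "fiq_config_error")
  }
  composition[idx, , drop = FALSE]
}
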