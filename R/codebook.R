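#' Load a 16-FIQ codebook
#'
#' The codebook defines, for each of the 16 questionnaire items, its answer
#' categories and their numeric midpoints (frequency items), its allowed
#' choices (choice items), or its numeric answer fields (open items), plus
#' the food-composition item each answer maps to.  The package ships a
#' documented default codebook; the original questionnaire's verbatim
#' category lists were never published in transcribable form, so the default
#' is an explicit, replaceable stand-in rather than a transcription.
#'
#' Frequency midpoints are stored with their reporting period; conversion to
#' per-day rates divides weekly midpoints by 7 and monthly midpoints by 30
#' (see [frequency_to_daily()]).
#'
#' @param path Path to a codebook YAML file, or `NULL` for the packaged
#'   default.
#' @return An object of class `fiq_codebook`: a validated list with one
#'   entry per questionnaire item.
#' @export
#' @examples
#' cb <- fiq_codebook()
#' length(cb$items)  # 16
fiq_codebook <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codebook.yaml", package = "fiq16")
  }
  raw <- yaml::read_yaml(path)
  validate_codebook(raw)
}

#' @rdname fiq_codebook
#' @param x A parsed codebook list, as read from YAML.
#' @export
validate_codebook <- function(x) {
  if (is.null(x$items)) .fiq_stop("codebook has no `items` section", "fiq_codebook_error")
  items <- x$items
  if (length(items) != 16L) {
    .fiq_stop(
      sprintf("codebook must define exactly 16 items, found %d (missing item?)", length(items)),
      "fiq_codebook_error"
    )
  }
  for (id in names(items)) {
    it <- items[[id]]
    if (is.null(it$type) || !it$type %in% c("frequency", "choice", "open")) {
      .fiq_stop(sprintf("item '%s': unknown type '%s'", id, it$type %||% "<missing>"),
                "fiq_codebook_error")
    }
    if (it$type == "frequency") {
      cats <- dplyr::bind_rows(lapply(it$categories, tibble::as_tibble))
      if (anyDuplicated(cats$code)) {
        .fiq_stop(sprintf("item '%s': duplicate categories", id), "fiq_codebook_error")
      }
      daily <- cats$midpoint / period_divisor(cats$per, id)
      if (any(diff(daily) <= 0)) {
        .fiq_stop(sprintf("item '%s': category midpoints not strictly increasing (per day)", id),
                  "fiq_codebook_error")
      }
      items[[id]]$categories <- cats
    }
    if (it$type == "choice" && anyDuplicated(unlist(it$choices))) {
      .fiq_stop(sprintf("item '%s': duplicate choices", id), "fiq_codebook_error")
    }
    if (it$type == "open" && length(it$fields) == 0) {
      .fiq_stop(sprintf("item '%s': open item without fields", id), "fiq_codebook_error")
    }
  }
  structure(list(version = x$version %||% 1, items = items), class = "fiq_codebook")
}

period_divisor <- function(per, item = "?") {
  div <- c(day = 1, week = 7, month = 30)[per]
  if (anyNA(div)) {
    .fiq_stop(sprintf("item '%s': unknown period '%s'", item,
                      paste(per[is.na(div)], collapse = ",")), "fiq_codebook_error")
  }
  unname(div)
}

#' Convert a frequency category to a per-day rate
#'
#' Looks up the category midpoint in the codebook and converts it to times
#' per day: weekly midpoints are divided by 7 and monthly midpoints by 30.
#'
#' @param category Character vector of category codes.
#' @param item Codebook item id (e.g. `"fruits_berries"`).
#' @param codebook An [fiq_codebook()] object.
#' @return Numeric vector of daily rates.
#' @export
#' @examples
#' frequency_to_daily("1-2/week", "fruits_berries")  # 1.5 / 7
frequency_to_daily <- function(category, item, codebook = fiq_codebook()) {
  it <- codebook$items[[item]]
  if (is.null(it) || it$type != "frequency") {
    .fiq_stop(sprintf("'%s' is not a frequency item", item), "fiq_coding_error")
  }
  idx <- match(category, it$categories$code)
  if (anyNA(idx)) {
    .fiq_stop(sprintf("item '%s': unknown category '%s'", item,
                      paste(unique(category[is.na(idx)]), collapse = ", ")),
              "fiq_coding_error")
  }
  it$categories$midpoint[idx] / period_divisor(it$categories$per[idx], item)
}

#' @export
print.fiq_codebook <- function(x, ...) {
  types <- vapply(x$items, function(i) i$type, character(1))
  cat("<fiq_codebook> 16 items:",
      sum(types == "frequency"), "frequency,",
      sum(types == "choice"), "choice,",
      sum(types == "open"), "open\n")
  invisible(x)
}

# map: response column -> composition item id / reporting period,
# derived from the codebook's open + frequency items
codebook_field_map <- function(codebook) {
  rows <- list()
  for (id in names(codebook$items)) {
    it <- codebook$items[[id]]
    if (it$type == "frequency") {
      rows[[id]] <- tibble(
        column = it$column, item = id, kind = "frequency",
        per = NA_character_, composition = it$composition %||% NA_character_
      )
    } else if (it$type == "open") {
      rows[[id]] <- tibble(
        column = names(it$fields), item = id, kind = "open", per = it$per,
        composition = vapply(it$fields, function(f) f$composition, character(1))
      )
    }
  }
  dplyr::bind_rows(rows)
}

choice_columns <- function(codebook) {
  items <- purrr::keep(codebook$items, ~ .x$type == "choice")
  setNames(vapply(items, function(i) i$column, character(1)), names(items))
}
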