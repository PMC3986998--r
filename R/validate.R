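#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors with average ranks for ties, computes the Pearson
#' correlation of the ranks, and a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite values.
#' @param alpha Significance level for the reported flag.
#' @return A one-row tibble: `r_s`, `p_value`, `significant`, `n`.
#' @export
#' @examples
#' spearman_rs(1:10, (1:10)^2)  # r_s = 1: rank correlation ignores monotone transforms
spearman_rs <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) .fiq_stop("x and y must have equal length", "fiq_domain_error")
  n <- length(x)
  if (n < 3) .fiq_stop("need at least 3 paired observations", "fiq_domain_error")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    .fiq_stop("values must be finite", "fiq_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    .fiq_stop("correlation undefined for a constant vector", "fiq_degenerate_error")
  }
  rs <- cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
  p <- if (abs(rs) >= 1) 0 else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r_s = rs, p_value = p, significant = p < alpha, n = n)
}

#' Rank-based tertile assignment
#'
#' Splits a cohort into three ordered groups whose sizes differ by at most
#' one, with the larger groups at the lower end (77 participants give
#' 26/26/25).  Ties are broken by stable original order, so a participant
#' sitting exactly on a cut goes to the lower tertile; an all-equal vector
#' is labelled deterministically by position, with a warning.
#'
#' @param values Numeric vector, length >= 3.
#' @return Integer labels in `{1, 2, 3}` (1 = lowest intake).
#' @export
#' @examples
#' assign_tertiles(c(10, 1, 5, 7, 2, 9))
assign_tertiles <- function(values) {
  n <- length(values)
  if (n < 3) .fiq_stop("need at least 3 values for tertiles", "fiq_domain_error")
  if (any(!is.finite(values))) .fiq_stop("values must be finite", "fiq_domain_error")
  if (length(unique(values)) == 1L) {
    warn("all values equal: tertiles assigned by stable input order")
  }
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  labels <- integer(n)
  labels[order(values, seq_along(values))] <- rep.int(1:3, sizes)
  labels
}

#' Tertile cross-classification
#'
#' Tabulates paired tertile labels into a 3x3 table and reports exact
#' agreement (diagonal share) and opposite misclassification (share of
#' pairs landing in opposite extreme tertiles), both as percentages.
#'
#' @param labels_a,labels_b Integer labels in `{1, 2, 3}`, equal length.
#' @return A list: `table` (3x3 matrix, rows = `labels_a`), `exact_pct`,
#'   `opposite_pct`, `n`.
#' @export
cross_classification <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    .fiq_stop("label vectors must have equal length", "fiq_domain_error")
  }
  if (!all(labels_a %in% 1:3) || !all(labels_b %in% 1:3)) {
    .fiq_stop("labels must be in {1, 2, 3}", "fiq_coding_error")
  }
  tab <- table(factor(labels_a, levels = 1:3), factor(labels_b, levels = 1:3))
  tab <- matrix(as.integer(tab), 3, 3, dimnames = list(a = 1:3, b = 1:3))
  n <- length(labels_a)
  list(
    table = tab,
    exact_pct = 100 * sum(diag(tab)) / n,
    opposite_pct = 100 * (tab[1, 3] + tab[3, 1]) / n,
    n = n
  )
}

#' Weighted kappa for a 3x3 agreement table
#'
#' Chance-corrected agreement for ordered categories,
#' `kappa_w = 1 - sum(w * o) / sum(w * e)`, with expected counts `e` from
#' the row/column marginals and disagreement weights
#' `w_ij = |i - j| / 2` (linear, the default) or `(i - j)^2 / 4`
#' (quadratic).  Perfect agreement gives 1; a table equal to the outer
#' product of its marginals gives 0.
#'
#' @param tab A 3x3 matrix of nonnegative counts.
#' @param scheme `"linear"` or `"quadratic"` weighting.
#' @return The weighted kappa, in `[-1, 1]`.
#' @export
#' @examples
#' weighted_kappa(diag(c(5, 5, 5)))  # 1
weighted_kappa <- function(tab, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3, 3))) .fiq_stop("need a 3x3 table", "fiq_domain_error")
  if (any(tab < 0) || any(!is.finite(tab))) .fiq_stop("counts must be finite and >= 0", "fiq_domain_error")
  n <- sum(tab)
  if (n < 1) .fiq_stop("empty table", "fiq_domain_error")
  d <- abs(outer(1:3, 1:3, "-"))
  w <- if (scheme == "linear") d / 2 else d^2 / 4
  obs <- sum(w * tab)
  if (obs == 0) return(1)  # all mass on the diagonal
  e <- outer(rowSums(tab), colSums(tab)) / n
  1 - obs / sum(w * e)
}

#' Questionnaire-side food-group frequencies
#'
#' Extracts one numeric consumption indicator per food group from a
#' response table, in the questionnaire's native units (frequency-category
#' midpoints per day, dish counts per week, slices/decilitres/glasses per
#' day), for rank-correlation against food-record grams per day.
#'
#' @inheritParams validate_responses
#' @return A tibble: `participant_id` plus one column per food group.
#' @export
fiq_food_group_frequencies <- function(responses, codebook = fiq_codebook()) {
  r <- validate_responses(responses, codebook)
  freq <- function(col, item) frequency_to_daily(r[[col]], item, codebook)
  tibble(
    participant_id = r$participant_id,
    fish_dishes = r$dishes_fish, sausage_dishes = r$dishes_sausage,
    poultry_dishes = r$dishes_chicken, meat_dishes = r$dishes_meat,
    vegetable_dishes = r$dishes_vegetable,
    fast_foods = freq("freq_fastfood", "fast_food"),
    vegetables = freq("freq_vegetable", "vegetables"),
    fruits_berries = freq("freq_fruit", "fruits_berries"),
    milk_products = r$milk_fat_free_dl + r$milk_low_fat_dl + r$milk_whole_dl,
    rye_breads = r$bread_rye_crisp_slices,
    multigrain_breads = r$bread_multigrain_slices,
    white_breads = r$bread_white_slices,
    porridges = r$cereal_porridge_dl,
    breakfast_cereals = r$cereal_flakes_dl,
    cheeses = r$cheese_low_fat_slices + r$cheese_regular_slices,
    cold_cuts = r$coldcut_low_fat_slices + r$coldcut_regular_slices +
      r$coldcut_frankfurter_slices,
    desserts = freq("freq_sugar_rich", "sugar_rich_foods"),
    sweets_sugar = freq("freq_sweets", "sweets"),
    tea = r$bev_tea_cups, coffee = r$bev_coffee_cups,
    soft_drinks = r$bev_soft_drink_glasses,
    sugar_sweetened_juices = r$bev_sweetened_juice_glasses,
    fruit_juices = r$bev_fruit_juice_glasses,
    beer = r$bev_beer_bottles, wine = r$bev_wine_glasses,
    spirits = r$bev_spirits_servings
  )
}

#' The 26 reference food groups
#'
#' Food-group keys of the reference food-record summaries, in reporting
#' order.
#' @return A character vector of 26 group ids.
#' @export
food_groups <- function() {
  c("fish_dishes", "sausage_dishes", "poultry_dishes", "meat_dishes",
    "vegetable_dishes", "fast_foods", "vegetables", "fruits_berries",
    "milk_products", "rye_breads", "multigrain_breads", "white_breads",
    "porridges", "breakfast_cereals", "cheeses", "cold_cuts", "desserts",
    "sweets_sugar", "tea", "coffee", "soft_drinks", "sugar_sweetened_juices",
    "fruit_juices", "beer", "wine", "spirits")
}

# nutrient columns compared between the two instruments (reference layout)
validation_nutrients <- function() {
  c("energy_kj", "fat_epct", "saturated_fat_epct", "protein_epct",
    "carbohydrate_epct", "sucrose_epct", "fibre_g", "alcohol_epct",
    "vitamin_d_ug", "vitamin_c_mg", "calcium_mg", "iron_mg")
}

#' Validate questionnaire estimates against food-record references
#'
#' Runs the full agreement analysis between paired instruments: per food
#' group, the Spearman correlation between questionnaire frequencies and
#' record grams per day; per nutrient, the Spearman correlation plus a
#' tertile cross-classification with exact/opposite agreement and weighted
#' kappa.  Participants are matched by `participant_id`; an id present in
#' only one table is an error.  Rows flagged `zero_energy` in the
#' questionnaire estimates are dropped (with a message) before comparison.
#'
#' @param estimates Questionnaire-side tibble from [estimate_nutrients()]
#'   (nutrient analysis), or `NULL` to skip nutrients.
#' @param references Food-record summaries: `participant_id`, the 26 food
#'   group columns (g/day) and the 12 nutrient columns.
#' @param frequencies Questionnaire-side food-group frequencies from
#'   [fiq_food_group_frequencies()], or `NULL` to skip food groups.
#' @param kappa_scheme Weighting scheme recorded and used for all kappas.
#' @param alpha Significance level.
#' @return An object of class `fiq_validation`: a list with tibbles
#'   `food_group_results` and `nutrient_results` (columns `id`, `r_s`,
#'   `p_value`, `significant`, and for nutrients `exact_pct`,
#'   `opposite_pct`, `weighted_kappa`), the 3x3 `cross_tables`, `n`, and
#'   the `kappa_scheme` used.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 30, seed = 7))
#' rep <- fiq_validate(
#'   estimates = estimate_nutrients(cohort$responses),
#'   references = cohort$records,
#'   frequencies = fiq_food_group_frequencies(cohort$responses)
#' )
#' rep$food_group_results
fiq_validate <- function(estimates = NULL, references = NULL, frequencies = NULL,
                         kappa_scheme = c("linear", "quadratic"), alpha = 0.05) {
  kappa_scheme <- match.arg(kappa_scheme)
  if (is.null(references)) .fiq_stop("reference food-record table required", "fiq_domain_error")
  references <- as_tibble(references)

  match_ids <- function(a, b, what) {
    only_a <- setdiff(a$participant_id, b$participant_id)
    only_b <- setdiff(b$participant_id, a$participant_id)
    if (length(only_a) + length(only_b) > 0) {
      .fiq_stop(paste0("unmatched participants in ", what, ": ",
                       paste(c(only_a, only_b), collapse = ", ")),
                "fiq_match_error")
    }
    b[match(a$participant_id, b$participant_id), ]
  }

  # a variable constant on either side (e.g. nobody reports spirits) has no
  # defined rank correlation; report NA for it rather than failing the run
  safe_spearman <- function(x, y, id) {
    tryCatch(
      spearman_rs(x, y, alpha = alpha),
      fiq_degenerate_error = function(e) {
        inform(sprintf("'%s': constant values, correlation undefined", id))
        tibble(r_s = NA_real_, p_value = NA_real_, significant = NA,
               n = length(x))
      }
    )
  }

  fg_results <- NULL
  if (!is.null(frequencies)) {
    frequencies <- as_tibble(frequencies)
    ref <- match_ids(frequencies, references, "food-group comparison")
    groups <- intersect(food_groups(), intersect(names(frequencies), names(ref)))
    fg_results <- purrr::map_dfr(groups, function(g) {
      res <- safe_spearman(frequencies[[g]], ref[[g]], g)
      mutate(res, id = g, .before = 1)
    })
  }

  nut_results <- NULL
  cross_tables <- list()
  n_used <- NA_integer_
  if (!is.null(estimates)) {
    estimates <- as_tibble(estimates)
    if ("zero_energy" %in% names(estimates) && any(estimates$zero_energy)) {
      inform(sprintf("dropping %d zero-energy participant(s) from validation",
                     sum(estimates$zero_energy)))
      estimates <- filter(estimates, !.data$zero_energy)
    }
    ref <- match_ids(estimates, references, "nutrient comparison")
    nutrients <- intersect(validation_nutrients(), intersect(names(estimates), names(ref)))
    n_used <- nrow(estimates)
    nut_results <- purrr::map_dfr(nutrients, function(nu) {
      res <- safe_spearman(estimates[[nu]], ref[[nu]], nu)
      ta <- assign_tertiles(estimates[[nu]])
      tb <- assign_tertiles(ref[[nu]])
      cc <- cross_classification(ta, tb)
      cross_tables[[nu]] <<- cc$table
      mutate(res, id = nu, .before = 1) %>%
        mutate(exact_pct = cc$exact_pct, opposite_pct = cc$opposite_pct,
               weighted_kappa = weighted_kappa(cc$table, kappa_scheme))
    })
  }

  structure(
    list(food_group_results = fg_results, nutrient_results = nut_results,
         cross_tables = cross_tables, n = n_used, kappa_scheme = kappa_scheme),
    class = "fiq_validation"
  )
}

#' @export
print.fiq_validation <- function(x, ...) {
  cat("<fiq_validation> n =", x$n, "| kappa:", x$kappa_scheme, "\n")
  if (!is.null(x$food_group_results)) {
    cat("food groups:", nrow(x$food_group_results), "| median r_s =",
        signif(stats::median(x$food_group_results$r_s, na.rm = TRUE), 2), "\n")
  }
  if (!is.null(x$nutrient_results)) {
    print(x$nutrient_results, n = Inf)
  }
  invisible(x)
}

#' Plot a validation report
#'
#' Dot plot of Spearman correlations per food group and per nutrient, with
#' exact-agreement percentages annotated for nutrients.
#'
#' @param object An `fiq_validation` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiq_validation <- function(object, ...) {
  parts <- list()
  if (!is.null(object$food_group_results)) {
    parts$`food group` <- object$food_group_results[, c("id", "r_s")]
  }
  if (!is.null(object$nutrient_results)) {
    parts$nutrient <- object$nutrient_results[, c("id", "r_s")]
  }
  df <- dplyr::bind_rows(parts, .id = "panel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_s,
                                   y = stats::reorder(.data$id, .data$r_s))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Spearman r_s (questionnaire vs food record)", y = NULL) +
    ggplot2::xlim(-1, 1)
}

#' @export
#' @rdname tidy.fiq_model
tidy.fiq_validation <- function(x, ...) {
  dplyr::bind_rows(
    `food_group` = x$food_group_results,
    nutrient = x$nutrient_results,
    .id = "level"
  )
}

#' Write a validation report to disk
#'
#' Writes the food-group and nutrient agreement tables as delimited text
#' and, when `jsonlite` is available, a machine-readable JSON report with
#' the cross-classification tables.
#'
#' @param report An `fiq_validation` object.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir, delim = ",") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(report$food_group_results)) {
    p <- file.path(dir, "food_group_agreement.csv")
    readr::write_delim(report$food_group_results, p, delim = delim)
    paths <- c(paths, p)
  }
  if (!is.null(report$nutrient_results)) {
    p <- file.path(dir, "nutrient_agreement.csv")
    readr::write_delim(report$nutrient_results, p, delim = delim)
    paths <- c(paths, p)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "validation_report.json")
    jsonlite::write_json(
      list(n = report$n, kappa_scheme = report$kappa_scheme,
           food_groups = report$food_group_results,
           nutrients = report$nutrient_results,
           cross_tables = lapply(report$cross_tables, unclass)),
      p, auto_unbox = TRUE, digits = NA
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}
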