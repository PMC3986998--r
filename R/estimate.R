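#' Estimation configuration
#'
#' Bundles the composition table with the portion sizes used by the three
#' add-on rules: grams of spread per bread slice, grams of cooking fat per
#' cooked dish, and grams of dressing per use.  Defaults are taken from the
#' composition table's own portion weights for the corresponding items.
#'
#' @param composition A composition table from [read_composition()].
#' @param spread_portion_g Grams of spread added per bread slice.
#' @param cooking_fat_portion_g Grams of cooking fat per cooked dish.
#' @param dressing_portion_g Grams of dressing per daily use.
#' @return A list of class `fiq_estimation_config`.
#' @export
estimation_config <- function(composition = read_composition(),
                              spread_portion_g = NULL,
                              cooking_fat_portion_g = NULL,
                              dressing_portion_g = NULL) {
  portion_of <- function(id) composition$portion_g[match(id, composition$item_id)]
  cfg <- list(
    composition = composition,
    spread_portion_g = spread_portion_g %||% portion_of("spread_margarine"),
    cooking_fat_portion_g = cooking_fat_portion_g %||% portion_of("cooking_oil"),
    dressing_portion_g = dressing_portion_g %||% portion_of("dressing_oil")
  )
  if (any(unlist(cfg[-1]) <= 0) || anyNA(unlist(cfg[-1]))) {
    .fiq_stop("rule portions must be positive", "fiq_config_error")
  }
  structure(cfg, class = "fiq_estimation_config")
}

#' Estimated daily food quantities
#'
#' Converts questionnaire answers into grams per day per food item:
#' frequency answers become daily rates (codebook midpoints, weekly / 7,
#' monthly / 30) multiplied by the item's average portion weight; open
#' counts are multiplied by the per-unit weight; and the three add-on rules
#' contribute spread (portion x bread slices, if a spread is used), cooking
#' fat (cooked dishes per week / 7 x portion, by reported fat type) and
#' salad dressing (one portion per day if a dressing is used).  Cream in
#' cooking contributes via its codebook portions-per-week mapping.
#'
#' @inheritParams validate_responses
#' @param config An [estimation_config()].
#' @return A long tibble: `participant_id`, `item` (composition item id),
#'   `g_per_day`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' estimate_food_quantities(cohort$responses)
estimate_food_quantities <- function(responses, codebook = fiq_codebook(),
                                     config = estimation_config()) {
  responses <- validate_responses(responses, codebook)
  comp <- config$composition
  fm <- codebook_field_map(codebook)
  out <- vector("list", nrow(fm) + 4L)

  for (i in seq_len(nrow(fm))) {
    row <- fm[i, ]
    entry <- composition_lookup(comp, row$composition,
                                context = paste0("item '", row$item, "'"))
    rate <- if (row$kind == "frequency") {
      frequency_to_daily(responses[[row$column]], row$item, codebook)
    } else {
      responses[[row$column]] / period_divisor(row$per, row$item)
    }
    out[[i]] <- tibble(
      participant_id = responses$participant_id,
      item = row$composition,
      g_per_day = rate * entry$portion_g
    )
  }
  n_base <- nrow(fm)
  out[[n_base + 1L]] <- apply_spread_rule(responses, codebook, config)
  out[[n_base + 2L]] <- apply_cooking_fat_rule(responses, codebook, config)
  out[[n_base + 3L]] <- apply_dressing_rule(responses, codebook, config)
  out[[n_base + 4L]] <- apply_cream_rule(responses, codebook, config)
  dplyr::bind_rows(out)
}

#' Spread, cooking-fat and dressing rules
#'
#' The three add-on rules of the estimation procedure, exposed
#' individually.  Each returns a long tibble (`participant_id`, `item`,
#' `g_per_day`); participants whose answer is `none` get zero grams.
#'
#' @inheritParams estimate_food_quantities
#' @name estimation_rules
NULL

#' @rdname estimation_rules
#' @export
apply_spread_rule <- function(responses, codebook = fiq_codebook(),
                              config = estimation_config()) {
  it <- codebook$items$spread_on_bread
  slices <- responses$bread_rye_crisp_slices + responses$bread_multigrain_slices +
    responses$bread_white_slices
  type <- responses[[it$column]]
  item <- dplyr::recode(type, !!!it$composition_by_choice, none = NA_character_)
  g <- ifelse(type == "none", 0, slices * config$spread_portion_g)
  tibble(participant_id = responses$participant_id,
         item = ifelse(is.na(item), "spread_margarine", item), g_per_day = g)
}

#' @rdname estimation_rules
#' @export
apply_cooking_fat_rule <- function(responses, codebook = fiq_codebook(),
                                   config = estimation_config()) {
  it <- codebook$items$cooking_fat
  dishes_per_week <- responses$dishes_fish + responses$dishes_sausage +
    responses$dishes_chicken + responses$dishes_meat + responses$dishes_vegetable
  type <- responses[[it$column]]
  item <- dplyr::recode(type, !!!it$composition_by_choice, none = NA_character_)
  g <- ifelse(type == "none", 0, dishes_per_week / 7 * config$cooking_fat_portion_g)
  tibble(participant_id = responses$participant_id,
         item = ifelse(is.na(item), "cooking_oil", item), g_per_day = g)
}

#' @rdname estimation_rules
#' @export
apply_dressing_rule <- function(responses, codebook = fiq_codebook(),
                                config = estimation_config()) {
  it <- codebook$items$salad_dressing
  type <- responses[[it$column]]
  item <- dplyr::recode(type, !!!it$composition_by_choice, none = NA_character_)
  g <- ifelse(type == "none", 0, config$dressing_portion_g)
  tibble(participant_id = responses$participant_id,
         item = ifelse(is.na(item), "dressing_oil", item), g_per_day = g)
}

apply_cream_rule <- function(responses, codebook, config) {
  it <- codebook$items$cream_in_cooking
  per_week <- unlist(it$portions_per_week)[responses[[it$column]]]
  entry <- composition_lookup(config$composition, it$composition, "cream rule")
  tibble(participant_id = responses$participant_id, item = it$composition,
         g_per_day = unname(per_week) / 7 * entry$portion_g)
}

#' Energy from macronutrient grams
#'
#' Energy (kJ) = 37 x fat + 17 x carbohydrate + 17 x protein +
#' 29 x alcohol.  Sucrose is a subset of carbohydrate and therefore
#' contributes through the carbohydrate term only; counting it again would
#' break the conservation of energy shares at 100%.
#'
#' @param fat_g,carbohydrate_g,protein_g,alcohol_g Daily grams (vectors).
#' @return Energy in kJ per day.
#' @export
#' @examples
#' compute_energy(10, 10, 10, 10)  # 1000 kJ
compute_energy <- function(fat_g, carbohydrate_g, protein_g, alcohol_g) {
  args <- cbind(fat_g, carbohydrate_g, protein_g, alcohol_g)
  if (any(!is.finite(args)) || any(args < 0)) {
    .fiq_stop("macronutrient grams must be finite and >= 0", "fiq_domain_error")
  }
  .kj_factors[["fat"]] * fat_g + .kj_factors[["carbohydrate"]] * carbohydrate_g +
    .kj_factors[["protein"]] * protein_g + .kj_factors[["alcohol"]] * alcohol_g
}

#' Energy percentage of a nutrient
#'
#' E% = grams x kJ-per-gram factor / total energy x 100.
#'
#' @param nutrient_g Daily grams of the nutrient.
#' @param kj_per_g Energy factor (37 for fats, 17 for carbohydrate, sucrose
#'   and protein, 29 for alcohol).
#' @param energy_kj Total daily energy (must be > 0).
#' @return E% values.
#' @export
energy_percent <- function(nutrient_g, kj_per_g, energy_kj) {
  if (any(energy_kj <= 0)) {
    .fiq_stop("E% undefined at zero total energy", "fiq_domain_error")
  }
  nutrient_g * kj_per_g / energy_kj * 100
}

#' Estimate daily nutrient intake from questionnaire answers
#'
#' Sums quantity x density / 100 over all estimated food quantities
#' (including the spread, cooking-fat, dressing and cream rules), then
#' derives energy (kJ) with the 37/17/29 factors and the energy shares
#' (E%) of fat, saturated fat, protein, carbohydrate, sucrose and alcohol.
#' Participants with zero estimated energy are flagged
#' (`zero_energy = TRUE`) with undefined (`NA`) energy shares; downstream
#' stages skip flagged rows.
#'
#' @inheritParams estimate_food_quantities
#' @return A tibble, one row per participant: gram/microgram/milligram
#'   intakes, `energy_kj`, the six `*_epct` shares and `zero_energy`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' estimate_nutrients(cohort$responses)
estimate_nutrients <- function(responses, codebook = fiq_codebook(),
                               config = estimation_config()) {
  q <- estimate_food_quantities(responses, codebook, config)
  comp <- config$composition
  dens_cols <- c(fat_g = "fat_g", saturated_fat_g = "saturated_fat_g",
                 protein_g = "protein_g", carbohydrate_g = "carbohydrate_g",
                 sucrose_g = "sucrose_g", fibre_g = "fibre_g", alcohol_g = "alcohol_g",
                 vitamin_d_ug = "vitamin_d_ug", vitamin_c_mg = "vitamin_c_mg",
                 calcium_mg = "calcium_mg", iron_mg = "iron_mg")
  joined <- dplyr::left_join(q, comp, by = c(item = "item_id"))
  totals <- joined %>%
    group_by(.data$participant_id) %>%
    summarise(across(all_of(unname(dens_cols)), ~ sum(.x * g_per_day / 100)),
              .groups = "drop")
  # preserve input participant order
  totals <- totals[match(responses$participant_id, totals$participant_id), ]
  add_energy_shares(totals)
}

# shared by the estimator and the synthetic record generator
add_energy_shares <- function(totals) {
  totals$energy_kj <- compute_energy(totals$fat_g, totals$carbohydrate_g,
                                     totals$protein_g, totals$alcohol_g)
  totals$zero_energy <- totals$energy_kj <= 0
  ep <- function(g, nutrient) {
    ifelse(totals$zero_energy, NA_real_,
           g * .kj_factors[[nutrient]] / ifelse(totals$zero_energy, 1, totals$energy_kj) * 100)
  }
  totals$fat_epct <- ep(totals$fat_g, "fat")
  totals$saturated_fat_epct <- ep(totals$saturated_fat_g, "saturated_fat")
  totals$protein_epct <- ep(totals$protein_g, "protein")
  totals$carbohydrate_epct <- ep(totals$carbohydrate_g, "carbohydrate")
  totals$sucrose_epct <- ep(totals$sucrose_g, "sucrose")
  totals$alcohol_epct <- ep(totals$alcohol_g, "alcohol")
  if (any(totals$zero_energy)) {
    warn(sprintf("%d participant(s) with zero estimated energy flagged; E%% undefined",
                 sum(totals$zero_energy)))
  }
  totals
}
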