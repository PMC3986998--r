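#' Per-food-group generator parameters
#'
#' Default latent-intake parameters of the synthetic cohort: the median
#' daily intake in grams, the between-person log-scale SD, the
#' within-person day-to-day log-scale SD (the 7-day food record averages
#' over this), and the target Spearman correlation between the
#' questionnaire and record instruments.  Default targets are the
#' validation-study correlations the generator is meant to emulate
#' (0.08-0.75 across groups); medians are plausible adult intakes chosen
#' so simulated record nutrients land near typical Finnish levels.
#'
#' @return A tibble: `group`, `median_g`, `sd_log`, `day_sd`, `target_rho`.
#' @export
default_group_params <- function() {
  tibble::tribble(
    ~group,                    ~median_g, ~target_rho,
    "fish_dishes",                  55,    0.57,
    "sausage_dishes",               40,    0.14,
    "poultry_dishes",               35,    0.08,
    "meat_dishes",                  80,    0.28,
    "vegetable_dishes",             60,    0.35,
    "fast_foods",                   30,    0.13,
    "vegetables",                  150,    0.36,
    "fruits_berries",              120,    0.65,
    "milk_products",               400,    0.68,
    "rye_breads",                   60,    0.59,
    "multigrain_breads",            30,    0.29,
    "white_breads",                 40,    0.42,
    "porridges",                   100,    0.65,
    "breakfast_cereals",            15,    0.63,
    "cheeses",                      30,    0.39,
    "cold_cuts",                    25,    0.46,
    "desserts",                     60,    0.57,
    "sweets_sugar",                 20,    0.48,
    "tea",                         150,    0.75,
    "coffee",                      450,    0.58,
    "soft_drinks",                 100,    0.49,
    "sugar_sweetened_juices",       50,    0.42,
    "fruit_juices",                100,    0.51,
    "beer",                        150,    0.61,
    "wine",                         30,    0.74,
    "spirits",                       5,    0.33
  ) %>%
    mutate(sd_log = 0.7, day_sd = 0.8, .after = "median_g")
}

#' Specify a synthetic paired cohort
#'
#' Describes a cohort of participants who completed both the questionnaire
#' and a 7-day food record.  Latent true intakes per food group are
#' log-normal; the record value is the mean of 7 daily draws around the
#' latent; the questionnaire answer is the codebook-discretized latent
#' perturbed by reporting noise whose size is derived from the target rank
#' correlation (see [generate_cohort()]).
#'
#' @param n Number of participants (default 77, the validation cohort
#'   size).
#' @param n_male Number of men (default 52; the remainder are women).
#' @param seed Integer seed; the cohort is fully deterministic given the
#'   spec.
#' @param groups Per-group parameter tibble, as [default_group_params()];
#'   override rows to tune individual correlations.
#' @param male_scale Multiplicative sex effect on intake medians (men eat
#'   more of most groups; fruits and vegetables are scaled inversely).
#' @return A list of class `fiq_cohort_spec`.
#' @export
cohort_spec <- function(n = 77, n_male = NULL, seed = 1L,
                        groups = default_group_params(), male_scale = 1.15) {
  if (n < 3) .fiq_stop("need n >= 3", "fiq_config_error")
  if (is.null(n_male)) n_male <- round(n * 52 / 77)
  if (n_male > n || n_male < 0) .fiq_stop("invalid n_male", "fiq_config_error")
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "median_g", "sd_log", "day_sd", "target_rho") %in% names(groups)))
  if (any(groups$sd_log < 0) || any(groups$day_sd < 0)) {
    .fiq_stop("SDs must be >= 0", "fiq_config_error")
  }
  if (any(abs(groups$target_rho) > 1)) {
    .fiq_stop("target correlations must be in [-1, 1]", "fiq_config_error")
  }
  structure(list(n = as.integer(n), n_male = as.integer(n_male),
                 seed = as.integer(seed), groups = groups,
                 male_scale = male_scale),
            class = "fiq_cohort_spec")
}

# Spearman target -> latent Pearson correlation (bivariate-normal identity),
# then divide out the attenuation from 7-day averaging of day-to-day noise
latent_correlation <- function(target_rho, sd_log, day_sd) {
  rho_p <- 2 * sin(pi * target_rho / 6)
  atten <- sd_log / sqrt(sd_log^2 + day_sd^2 / 7)
  pmin(1, pmax(-1, rho_p / atten))
}

# random per-participant shares across k classes (one class tends to
# dominate, as with milk fat classes in real cohorts)
class_shares <- function(n, k, shape = 0.6) {
  shape <- rep_len(shape, k)
  g <- matrix(0, n, k)
  for (j in seq_len(k)) g[, j] <- rgamma(n, shape = shape[j])
  g / rowSums(g)
}

snap_to_category <- function(rate_per_day, item, codebook) {
  cats <- codebook$items[[item]]$categories
  daily <- cats$midpoint / period_divisor(cats$per, item)
  cats$code[vapply(rate_per_day, function(r) which.min(abs(daily - r)), integer(1))]
}

#' Generate a synthetic paired cohort
#'
#' Draws, for every participant and food group, a latent log-normal true
#' intake; the food-record value is the mean of 7 daily log-normal draws
#' around it, and the questionnaire answer is the latent perturbed by
#' reporting noise and then discretized into the codebook's answer
#' categories and integer/half-unit counts.  The reporting-noise size is
#' derived from the group's target Spearman correlation: the target is
#' mapped to a latent Pearson correlation via `2 sin(pi rho / 6)` and
#' corrected for the attenuation caused by day-to-day variation, so the
#' realized questionnaire-vs-record rank correlation approaches the target
#' (discretization into answer categories attenuates it slightly).
#'
#' Record nutrient intakes are derived from the record food-group grams
#' through the composition table, so they are exactly consistent with the
#' generated grams by construction.
#'
#' @param spec A [cohort_spec()].
#' @param codebook An [fiq_codebook()].
#' @param composition A [read_composition()] table.
#' @return A list: `responses` (validated questionnaire table), `records`
#'   (food-record summaries: `participant_id`, 26 food-group gram columns,
#'   and the 12 reference nutrient columns), and `latent` (the
#'   questionnaire-side continuous grams per day before discretization
#'   into answer categories — a diagnostic of the generative mechanism;
#'   in the noise-free limit its ranks coincide with the record's).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 10, seed = 3))
#' names(cohort)
generate_cohort <- function(spec = cohort_spec(), codebook = fiq_codebook(),
                            composition = read_composition()) {
  set.seed(spec$seed)
  n <- spec$n
  sex <- c(rep("male", spec$n_male), rep("female", n - spec$n_male))
  ids <- sprintf("p%03d", seq_len(n))

  # latent, record and questionnaire-side values per group (grams/day)
  q_g <- rec_g <- matrix(NA_real_, n, nrow(spec$groups),
                         dimnames = list(NULL, spec$groups$group))
  for (i in seq_len(nrow(spec$groups))) {
    g <- spec$groups[i, ]
    sex_mult <- if (g$group %in% c("fruits_berries", "vegetables")) {
      ifelse(sex == "male", 1 / spec$male_scale, 1)
    } else {
      ifelse(sex == "male", spec$male_scale, 1)
    }
    mu <- log(g$median_g * sex_mult)
    latent <- rnorm(n, mu, g$sd_log)
    day_noise <- matrix(rnorm(n * 7, 0, g$day_sd), n, 7)
    rec_g[, i] <- rowMeans(exp(latent + day_noise))
    r <- latent_correlation(g$target_rho, g$sd_log, g$day_sd)
    q_log <- mu + r * (latent - mu) + g$sd_log * sqrt(1 - r^2) * rnorm(n)
    q_g[, i] <- exp(q_log)
  }

  portion <- function(id) composition$portion_g[match(id, composition$item_id)]
  round_half <- function(x) round(x * 2) / 2

  milk_sh <- class_shares(n, 3)
  cheese_sh <- class_shares(n, 2)
  coldcut_sh <- class_shares(n, 3, shape = c(1, 1, 0.4))

  responses <- tibble(
    participant_id = ids, sex = sex,
    meals_per_day = sample(c("1-2", "3-4", "5-6", "7+"), n, TRUE,
                           prob = c(0.1, 0.55, 0.3, 0.05)),
    freq_fastfood = snap_to_category(q_g[, "fast_foods"] / portion("fastfood"),
                                     "fast_food", codebook),
    freq_fruit = snap_to_category(q_g[, "fruits_berries"] / portion("fruit"),
                                  "fruits_berries", codebook),
    freq_vegetable = snap_to_category(q_g[, "vegetables"] / portion("vegetable"),
                                      "vegetables", codebook),
    freq_sugar_rich = snap_to_category(q_g[, "desserts"] / portion("sugar_rich"),
                                       "sugar_rich_foods", codebook),
    freq_sweets = snap_to_category(q_g[, "sweets_sugar"] / portion("sweets"),
                                   "sweets", codebook),
    cooking_fat_type = sample(c("vegetable_oil_or_margarine", "butter_or_butter_spread",
                                "other", "none"), n, TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    cream_in_cooking = sample(c("never", "sometimes", "regularly"), n, TRUE,
                              prob = c(0.5, 0.35, 0.15)),
    spread_on_bread_type = sample(c("vegetable_margarine", "butter_or_butter_spread",
                                    "none"), n, TRUE, prob = c(0.55, 0.3, 0.15)),
    dressing_type = sample(c("oil_based", "other", "none"), n, TRUE,
                           prob = c(0.4, 0.3, 0.3)),
    dishes_fish = round(pmax(0, q_g[, "fish_dishes"] / portion("dish_fish") * 7)),
    dishes_sausage = round(pmax(0, q_g[, "sausage_dishes"] / portion("dish_sausage") * 7)),
    dishes_chicken = round(pmax(0, q_g[, "poultry_dishes"] / portion("dish_chicken") * 7)),
    dishes_meat = round(pmax(0, q_g[, "meat_dishes"] / portion("dish_meat") * 7)),
    dishes_vegetable = round(pmax(0, q_g[, "vegetable_dishes"] / portion("dish_vegetable") * 7)),
    milk_fat_free_dl = round_half(q_g[, "milk_products"] / 100 * milk_sh[, 1]),
    milk_low_fat_dl = round_half(q_g[, "milk_products"] / 100 * milk_sh[, 2]),
    milk_whole_dl = round_half(q_g[, "milk_products"] / 100 * milk_sh[, 3]),
    cheese_low_fat_slices = round(q_g[, "cheeses"] / portion("cheese_low_fat") * cheese_sh[, 1]),
    cheese_regular_slices = round(q_g[, "cheeses"] / portion("cheese_regular") * cheese_sh[, 2]),
    coldcut_low_fat_slices = round(q_g[, "cold_cuts"] / portion("coldcut_low_fat") * coldcut_sh[, 1]),
    coldcut_regular_slices = round(q_g[, "cold_cuts"] / portion("coldcut_regular") * coldcut_sh[, 2]),
    coldcut_frankfurter_slices = round(q_g[, "cold_cuts"] / portion("coldcut_frankfurter") * coldcut_sh[, 3]),
    bread_rye_crisp_slices = round(q_g[, "rye_breads"] / portion("bread_rye_crisp")),
    bread_multigrain_slices = round(q_g[, "multigrain_breads"] / portion("bread_multigrain")),
    bread_white_slices = round(q_g[, "white_breads"] / portion("bread_white")),
    cereal_porridge_dl = round_half(q_g[, "porridges"] / portion("cereal_porridge")),
    cereal_flakes_dl = round_half(q_g[, "breakfast_cereals"] / portion("cereal_flakes")),
    bev_coffee_cups = round(q_g[, "coffee"] / portion("bev_coffee")),
    bev_tea_cups = round(q_g[, "tea"] / portion("bev_tea")),
    bev_soft_drink_glasses = round(q_g[, "soft_drinks"] / portion("bev_soft_drink")),
    bev_sweetened_juice_glasses = round(q_g[, "sugar_sweetened_juices"] / portion("bev_sweetened_juice")),
    bev_fruit_juice_glasses = round(q_g[, "fruit_juices"] / portion("bev_fruit_juice")),
    bev_beer_bottles = round(q_g[, "beer"] / portion("bev_beer")),
    bev_wine_glasses = round(q_g[, "wine"] / portion("bev_wine")),
    bev_spirits_servings = round(q_g[, "spirits"] / portion("bev_spirits"))
  )
  responses <- validate_responses(responses, codebook)

  records <- dplyr::bind_cols(
    tibble(participant_id = ids),
    as_tibble(rec_g),
    record_nutrients_from_groups(as_tibble(rec_g), composition)
  )
  latent <- dplyr::bind_cols(tibble(participant_id = ids), as_tibble(q_g))
  list(responses = responses, records = records, latent = latent)
}

#' Derive record nutrient intakes from food-group grams
#'
#' Maps each of the 26 food groups to a composition item and sums
#' grams x density / 100 into the 12 reference nutrients (with energy from
#' the 37/17/29 factors and the six energy shares).  Used by the cohort
#' generator; exposed so the group-to-nutrient consistency can be checked
#' independently.
#'
#' @param group_grams Tibble/matrix of food-group gram columns.
#' @param composition A composition table.
#' @return A tibble of nutrient columns (no `participant_id`).
#' @export
record_nutrients_from_groups <- function(group_grams, composition = read_composition()) {
  map <- c(
    fish_dishes = "dish_fish", sausage_dishes = "dish_sausage",
    poultry_dishes = "dish_chicken", meat_dishes = "dish_meat",
    vegetable_dishes = "dish_vegetable", fast_foods = "fastfood",
    vegetables = "vegetable", fruits_berries = "fruit",
    milk_products = "milk_low_fat", rye_breads = "bread_rye_crisp",
    multigrain_breads = "bread_multigrain", white_breads = "bread_white",
    porridges = "cereal_porridge", breakfast_cereals = "cereal_flakes",
    cheeses = "cheese_regular", cold_cuts = "coldcut_regular",
    desserts = "sugar_rich", sweets_sugar = "sweets",
    tea = "bev_tea", coffee = "bev_coffee", soft_drinks = "bev_soft_drink",
    sugar_sweetened_juices = "bev_sweetened_juice",
    fruit_juices = "bev_fruit_juice", beer = "bev_beer", wine = "bev_wine",
    spirits = "bev_spirits"
  )
  group_grams <- as_tibble(group_grams)
  groups <- intersect(names(map), names(group_grams))
  G <- as.matrix(group_grams[, groups, drop = FALSE])
  dens_cols <- c("fat_g", "saturated_fat_g", "protein_g", "carbohydrate_g",
                 "sucrose_g", "fibre_g", "alcohol_g", "vitamin_d_ug",
                 "vitamin_c_mg", "calcium_mg", "iron_mg")
  D <- as.matrix(composition_lookup(composition, unname(map[groups]),
                                    "record nutrients")[, dens_cols]) / 100
  totals <- as_tibble(as.data.frame(G %*% D))
  names(totals) <- dens_cols
  add_energy_shares(totals)
}

#' Generate data with a known scoring model
#'
#' Parameter-recovery harness for the multiplier search: item values are
#' drawn as small nonnegative counts (Poisson, mean 3), and the target is
#' `intercept + slope x sum(m_i x_i)` plus Gaussian noise.
#'
#' @param n Number of rows.
#' @param true_multipliers Named numeric vector of true integer weights.
#' @param intercept,slope Linear map from the true sum score to the target.
#' @param noise_sd Gaussian noise SD on the target.
#' @param seed Integer seed.
#' @return A tibble with one column per item plus `target`; the true
#'   configuration is stored in `attr(, "truth")`.
#' @export
generate_known_model_data <- function(n, true_multipliers, intercept = 0,
                                      slope = 1, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  items <- names(true_multipliers)
  if (is.null(items)) .fiq_stop("true_multipliers must be named", "fiq_config_error")
  X <- matrix(stats::rpois(n * length(items), lambda = 3), n, length(items),
              dimnames = list(NULL, items))
  sc <- drop(X %*% true_multipliers)
  out <- as_tibble(as.data.frame(X))
  out$target <- intercept + slope * sc + rnorm(n, 0, noise_sd)
  attr(out, "truth") <- list(multipliers = true_multipliers,
                             intercept = intercept, slope = slope,
                             noise_sd = noise_sd)
  out
}
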