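# a response with every count zeroed and all choices "none"/"never";
# individual answers are then switched on per test
blank_response <- function(id = "p1", sex = "male") {
  r <- example_participant()
  r$participant_id <- id
  r$sex <- sex
  r$freq_fruit <- "never"
  r$dishes_sausage <- 0
  r$cheese_regular_slices <- 0
  r$cooking_fat_type <- "none"
  r
}

quantity_of <- function(q, item, id = "p1") {
  rows <- q[q$item == item & q$participant_id == id, ]
  sum(rows$g_per_day)
}

test_that("food quantities follow frequency x portion and count x unit weight", {
  comp <- read_composition()
  portion <- function(it) comp$portion_g[comp$item_id == it]

  r <- blank_response()
  r$freq_fruit <- "1/day"        # 1 portion/day
  r$dishes_fish <- 2             # per week
  r$milk_low_fat_dl <- 2         # per day
  q <- estimate_food_quantities(r)

  expect_equal(quantity_of(q, "fruit"), 1 * portion("fruit"))
  expect_equal(quantity_of(q, "dish_fish"), 2 / 7 * portion("dish_fish"))
  expect_equal(quantity_of(q, "milk_low_fat"), 2 * portion("milk_low_fat"))
})

test_that("missing composition entries are a configuration error", {
  comp <- read_composition()
  cfg <- estimation_config(validate_composition(comp[comp$item_id != "fruit", ]))
  expect_error(estimate_food_quantities(blank_response(), config = cfg),
               "fruit", class = "fiq_config_error")
})

test_that("spread rule multiplies bread slices by the spread portion", {
  r <- blank_response()
  r$bread_white_slices <- 4
  cfg <- estimation_config(spread_portion_g = 5)

  r$spread_on_bread_type <- "none"
  expect_equal(sum(apply_spread_rule(r, config = cfg)$g_per_day), 0)

  r$spread_on_bread_type <- "vegetable_margarine"
  sp <- apply_spread_rule(r, config = cfg)
  expect_equal(sp$g_per_day, 20)
  expect_equal(sp$item, "spread_margarine")

  r$spread_on_bread_type <- "butter_or_butter_spread"
  r$bread_white_slices <- 0
  sp <- apply_spread_rule(r, config = cfg)
  expect_equal(sp$g_per_day, 0)
  expect_equal(sp$item, "spread_butter")
})

test_that("cooking-fat rule scales with weekly cooked dishes", {
  cfg <- estimation_config(cooking_fat_portion_g = 10)
  r <- blank_response()
  r$dishes_meat <- 7

  r$cooking_fat_type <- "none"
  expect_equal(sum(apply_cooking_fat_rule(r, config = cfg)$g_per_day), 0)

  r$cooking_fat_type <- "vegetable_oil_or_margarine"
  cf <- apply_cooking_fat_rule(r, config = cfg)
  expect_equal(cf$g_per_day, 10)
  expect_equal(cf$item, "cooking_oil")

  r$dishes_meat <- 7
  r$dishes_fish <- 7            # 14 dishes/week in total
  expect_equal(apply_cooking_fat_rule(r, config = cfg)$g_per_day, 20)
})

test_that("dressing rule adds one portion per day unless none", {
  cfg <- estimation_config(dressing_portion_g = 10)
  r <- blank_response()

  expect_equal(sum(apply_dressing_rule(r, config = cfg)$g_per_day), 0)

  r$dressing_type <- "oil_based"
  dr <- apply_dressing_rule(r, config = cfg)
  expect_equal(dr$g_per_day, 10)
  expect_equal(dr$item, "dressing_oil")

  r$dressing_type <- "other"
  dr <- apply_dressing_rule(r, config = cfg)
  expect_equal(dr$g_per_day, 10)
  expect_equal(dr$item, "dressing_other")
})

test_that("energy follows the 37/17/29 kJ factors", {
  expect_equal(compute_energy(10, 0, 0, 0), 370)
  expect_equal(compute_energy(0, 0, 0, 0), 0)
  expect_equal(compute_energy(10, 10, 10, 10), 1000)
  expect_error(compute_energy(-1, 0, 0, 0), class = "fiq_domain_error")
})

test_that("energy percentages normalize against total energy", {
  # fat-only diet
  expect_equal(energy_percent(10, 37, compute_energy(10, 0, 0, 0)), 100)
  expect_equal(energy_percent(0, 17, 540), 0)
  # fat 10 g + carb 10 g: fat share = 370/540
  expect_equal(energy_percent(10, 37, compute_energy(10, 10, 0, 0)),
               370 / 540 * 100)
  expect_error(energy_percent(10, 37, 0), class = "fiq_domain_error")
})

test_that("single-item intake matches density arithmetic (milk vitamin D)", {
  r <- blank_response()
  r$meals_per_day <- "1-2"        # meal_average has zero densities
  r$milk_low_fat_dl <- 2          # fixture: 100 g/dl, 1 ug vit D per 100 g
  est <- estimate_nutrients(r)
  expect_equal(est$vitamin_d_ug, 2)
})

test_that("estimated nutrients equal a naive per-item re-summation", {
  cohort <- generate_cohort(cohort_spec(n = 8, seed = 11))
  comp <- read_composition()
  est <- estimate_nutrients(cohort$responses)
  brute <- nutrients_brute(estimate_food_quantities(cohort$responses), comp)
  for (nc in colnames(brute)) {
    expect_equal(est[[nc]], unname(brute[, nc]), tolerance = 1e-12,
                 label = paste("naive re-summation of", nc))
  }
})

test_that("gram intakes are additive in counts and monotone in frequency", {
  a <- blank_response()
  a$dishes_fish <- 2; a$milk_whole_dl <- 1; a$bev_beer_bottles <- 1
  b <- blank_response()
  b$dishes_fish <- 3; b$cheese_regular_slices <- 4
  ab <- blank_response()
  ab$dishes_fish <- 5; ab$milk_whole_dl <- 1; ab$bev_beer_bottles <- 1
  ab$cheese_regular_slices <- 4

  gram_cols <- c("fat_g", "saturated_fat_g", "protein_g", "carbohydrate_g",
                 "sucrose_g", "fibre_g", "alcohol_g", "vitamin_d_ug",
                 "vitamin_c_mg", "calcium_mg", "iron_mg")
  ea <- estimate_nutrients(a); eb <- estimate_nutrients(b)
  eab <- estimate_nutrients(ab)
  base <- suppressWarnings(estimate_nutrients(blank_response()))  # zero energy
  for (nc in gram_cols) {
    expect_equal(eab[[nc]], ea[[nc]] + eb[[nc]] - base[[nc]],
                 tolerance = 1e-12, label = paste("additivity of", nc))
  }

  # raising fruit frequency can lower no gram-valued nutrient
  lo <- blank_response(); lo$freq_fruit <- "1-2/week"
  hi <- blank_response(); hi$freq_fruit <- "2/day"
  elo <- estimate_nutrients(lo); ehi <- estimate_nutrients(hi)
  for (nc in gram_cols) expect_gte(ehi[[nc]], elo[[nc]])
})

test_that("energy shares conserve to 100 and zero-energy rows are flagged", {
  cohort <- generate_cohort(cohort_spec(n = 40, seed = 3))
  est <- estimate_nutrients(cohort$responses)
  ok <- !est$zero_energy
  expect_true(any(ok))
  expect_equal(
    est$fat_epct[ok] + est$protein_epct[ok] + est$carbohydrate_epct[ok] +
      est$alcohol_epct[ok],
    rep(100, sum(ok)), tolerance = 1e-9
  )
  expect_true(all(est$sucrose_epct[ok] <= est$carbohydrate_epct[ok] + 1e-12))
  expect_true(all(est$saturated_fat_epct[ok] <= est$fat_epct[ok] + 1e-12))

  zero <- blank_response()
  zero$meals_per_day <- "1-2"
  expect_warning(ez <- estimate_nutrients(zero), "zero estimated energy")
  expect_true(ez$zero_energy)
  expect_true(is.na(ez$fat_epct))
})

test_that("spread type deterministically selects the fat class", {
  r <- blank_response()
  r$bread_rye_crisp_slices <- 2
  r$spread_on_bread_type <- "vegetable_margarine"
  expect_equal(apply_spread_rule(r)$item, "spread_margarine")
  r$spread_on_bread_type <- "butter_or_butter_spread"
  expect_equal(apply_spread_rule(r)$item, "spread_butter")
})
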