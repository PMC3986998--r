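# Default 16-FIQ codebook.
#
# The original questionnaire's verbatim category lists were never
# published in transcribable form; this codebook is a documented,
# replaceable stand-in covering every item the instrument is described
# as containing, including the answers of the published worked example.
# Swap in an exact transcription by passing another file of the same
# schema to fiq_codebook().
#
# Schema: 16 items keyed by id.
#   type: frequency -> one categorical column; categories have a
#         numeric midpoint and a period (day/week/month).
#   type: choice    -> one categorical column; `choices` is the allowed
#         set; optional `portions_per_week` maps a choice to a portion
#         rate used by nutrient estimation.
#   type: open      -> numeric columns (`fields`), each mapping to a
#         food-composition item; `per` is the reporting period.
version: 1
items:
  meals_per_day:
    type: frequency
    column: meals_per_day
    categories:
      - {code: "1-2", midpoint: 1.5, per: day}
      - {code: "3-4", midpoint: 3.5, per: day}
      - {code: "5-6", midpoint: 5.5, per: day}
      - {code: "7+",  midpoint: 7.0, per: day}
    composition: meal_average
  fast_food:
    type: frequency
    column: freq_fastfood
    categories:
      - {code: "never",        midpoint: 0.0, per: month}
      - {code: "1-3/month",    midpoint: 2.0, per: month}
      - {code: "1-3/week",     midpoint: 2.0, per: week}
      - {code: "4-6/week",     midpoint: 5.0, per: week}
      - {code: "daily",        midpoint: 1.0, per: day}
    composition: fastfood
  fruits_berries:
    type: frequency
    column: freq_fruit
    categories:
      - {code: "never",      midpoint: 0.0, per: month}
      - {code: "1-3/month",  midpoint: 2.0, per: month}
      - {code: "1-2/week",   midpoint: 1.5, per: week}
      - {code: "3-5/week",   midpoint: 4.0, per: week}
      - {code: "1/day",      midpoint: 1.0, per: day}
      - {code: "2/day",      midpoint: 2.0, per: day}
      - {code: "3+/day",     midpoint: 3.5, per: day}
    composition: fruit
  vegetables:
    type: frequency
    column: freq_vegetable
    categories:
      - {code: "never",      midpoint: 0.0, per: month}
      - {code: "1-3/month",  midpoint: 2.0, per: month}
      - {code: "1-2/week",   midpoint: 1.5, per: week}
      - {code: "3-5/week",   midpoint: 4.0, per: week}
      - {code: "1/day",      midpoint: 1.0, per: day}
      - {code: "2/day",      midpoint: 2.0, per: day}
      - {code: "3+/day",     midpoint: 3.5, per: day}
    composition: vegetable
  sugar_rich_foods:
    type: frequency
    column: freq_sugar_rich
    categories:
      - {code: "never",      midpoint: 0.0, per: month}
      - {code: "1-3/month",  midpoint: 2.0, per: month}
      - {code: "1-2/week",   midpoint: 1.5, per: week}
      - {code: "3-5/week",   midpoint: 4.0, per: week}
      - {code: "daily",      midpoint: 1.0, per: day}
      - {code: "2+/day",     midpoint: 2.5, per: day}
    composition: sugar_rich
  sweets:
    type: frequency
    column: freq_sweets
    categories:
      - {code: "never",      midpoint: 0.0, per: month}
      - {code: "1-3/month",  midpoint: 2.0, per: month}
      - {code: "1-2/week",   midpoint: 1.5, per: week}
      - {code: "3-5/week",   midpoint: 4.0, per: week}
      - {code: "daily",      midpoint: 1.0, per: day}
      - {code: "2+/day",     midpoint: 2.5, per: day}
    composition: sweets
  cooking_fat:
    type: choice
    column: cooking_fat_type
    choices: [vegetable_oil_or_margarine, butter_or_butter_spread, other, none]
    composition_by_choice:
      vegetable_oil_or_margarine: cooking_oil
      butter_or_butter_spread: cooking_butter
      other: cooking_other
  cream_in_cooking:
    type: choice
    column: cream_in_cooking
    choices: [never, sometimes, regularly]
    portions_per_week: {never: 0, sometimes: 1, regularly: 3}
    composition: cream
  spread_on_bread:
    type: choice
    column: spread_on_bread_type
    choices: [vegetable_margarine, butter_or_butter_spread, none]
    composition_by_choice:
      vegetable_margarine: spread_margarine
      butter_or_butter_spread: spread_butter
  salad_dressing:
    type: choice
    column: dressing_type
    choices: [oil_based, other, none]
    composition_by_choice:
      oil_based: dressing_oil
      other: dressing_other
  dishes_per_week:
    type: open
    per: week
    fields:
      dishes_fish:      {composition: dish_fish}
      dishes_sausage:   {composition: dish_sausage}
      dishes_chicken:   {composition: dish_chicken}
      dishes_meat:      {composition: dish_meat}
      dishes_vegetable: {composition: dish_vegetable}
  milk:
    type: open
    per: day
    fields:
      milk_fat_free_dl: {composition: milk_fat_free}
      milk_low_fat_dl:  {composition: milk_low_fat}
      milk_whole_dl:    {composition: milk_whole}
  cheese:
    type: open
    per: day
    fields:
      cheese_low_fat_slices: {composition: cheese_low_fat}
      cheese_regular_slices: {composition: cheese_regular}
  cold_cuts:
    type: open
    per: day
    fields:
      coldcut_low_fat_slices:     {composition: coldcut_low_fat}
      coldcut_regular_slices:     {composition: coldcut_regular}
      coldcut_frankfurter_slices: {composition: coldcut_frankfurter}
  bread_and_cereal:
    type: open
    per: day
    fields:
      bread_rye_crisp_slices:  {composition: bread_rye_crisp}
      bread_multigrain_slices: {composition: bread_multigrain}
      bread_white_slices:      {composition: bread_white}
      cereal_porridge_dl:      {composition: cereal_porridge}
      cereal_flakes_dl:        {composition: cereal_flakes}
  beverages:
    type: open
    per: day
    fields:
      bev_coffee_cups:            {composition: bev_coffee}
      bev_tea_cups:               {composition: bev_tea}
      bev_soft_drink_glasses:     {composition: bev_soft_drink}
      bev_sweetened_juice_glasses: {composition: bev_sweetened_juice}
      bev_fruit_juice_glasses:    {composition: bev_fruit_juice}
      bev_beer_bottles:           {composition: bev_beer}
      bev_wine_glasses:           {composition: bev_wine}
      bev_spirits_servings:       {composition: bev_spirits}
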