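participant_id,sex,cooking_fat_type,cream_in_cooking,spread_on_bread_type,dressing_type,meals_per_day,freq_fastfood,freq_fruit,freq_vegetable,freq_sugar_rich,freq_sweets,dishes_fish,dishes_sausage,dishes_chicken,dishes_meat,dishes_vegetable,milk_fat_free_dl,milk_low_fat_dl,milk_whole_dl,cheese_low_fat_slices,cheese_regular_slices,coldcut_low_fat_slices,coldcut_regular_slices,coldcut_frankfurter_slices,bread_rye_crisp_slices,bread_multigrain_slices,bread_white_slices,cereal_porridge_dl,cereal_flakes_dl,bev_coffee_cups,bev_tea_cups,bev_soft_drink_glasses,bev_sweetened_juice_glasses,bev_fruit_juice_glasses,bev_beer_bottles,bev_wine_glasses,bev_spirits_servings
worked-example,male,vegetable_oil_or_margarine,never,none,none,3-4,never,1/day,never,never,never,0,2,0,0,0,0,0,0,0,6,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
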