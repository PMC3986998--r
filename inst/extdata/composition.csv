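item_id,portion_g,fat_g,saturated_fat_g,protein_g,carbohydrate_g,sucrose_g,fibre_g,alcohol_g,vitamin_d_ug,vitamin_c_mg,calcium_mg,iron_mg
meal_average,0,0,0,0,0,0,0,0,0,0,0,0
fastfood,250,11,4,9,22,2,1.5,0,0.3,3,80,1.2
fruit,100,0.3,0.1,0.6,11,6,2.2,0,0,35,15,0.3
vegetable,80,0.2,0.05,1.5,4,1.5,2.5,0,0,25,30,0.6
sugar_rich,80,12,6,5,45,28,1,0,0.4,1,70,1
sweets,40,8,5,3,65,55,0.5,0,0,0,40,0.5
dish_fish,300,6,1.2,12,8,0.5,1,0,3.5,5,40,0.8
dish_sausage,300,12,4.8,9,9,0.8,1,0,0.4,4,30,1
dish_chicken,300,6,1.5,13,8,0.5,1,0,0.2,5,25,0.9
dish_meat,300,9,3.6,11,9,0.6,1.2,0,0.2,5,25,1.4
dish_vegetable,300,4,0.8,4,10,1.5,2.5,0,0.1,15,45,1
milk_fat_free,100,0.1,0.05,3.3,4.9,0,0,0,1,1,120,0.03
milk_low_fat,100,1.5,1,3.2,4.8,0,0,0,1,1,120,0.03
milk_whole,100,3.5,2.3,3.2,4.7,0,0,0,1,1,118,0.03
cheese_low_fat,10,17,11,30,1,0,0,0,0.3,0,900,0.4
cheese_regular,10,29,19,26,1,0,0,0,0.5,0,850,0.4
coldcut_low_fat,12,4,1.5,19,1.5,0.5,0,0,0.5,0,10,1.5
coldcut_regular,12,22,8.5,14,1.5,0.5,0,0,0.7,0,12,1.4
coldcut_frankfurter,15,20,7.5,11,4,0.5,0.3,0,0.6,0,30,1
bread_rye_crisp,25,1.8,0.3,8.5,45,1,11,0,0,0,30,2.8
bread_multigrain,30,3,0.5,9,44,1.5,6,0,0,0,40,2
bread_white,30,2.5,0.5,8,50,2.5,3,0,0,0,35,1.2
cereal_porridge,100,1.5,0.3,2.5,12,0.3,1.9,0,0,0,10,0.7
cereal_flakes,40,4,0.8,9,62,10,7.5,0,0,0,40,4
bev_coffee,150,0,0,0.2,0.3,0,0,0,0,0,4,0.01
bev_tea,200,0,0,0.1,0.2,0,0,0,0,0,2,0.01
bev_soft_drink,330,0,0,0,10.5,10.5,0,0,0,0,2,0
bev_sweetened_juice,200,0,0,0.1,11,9,0.1,0,0,15,5,0.1
bev_fruit_juice,200,0,0,0.5,9.5,6,0.2,0,0,30,10,0.2
bev_beer,330,0,0,0.4,3,0,0,3.7,0,0,4,0.02
bev_wine,120,0,0,0.1,2.5,0.5,0,10,0,0,8,0.4
bev_spirits,40,0,0,0,0.1,0,0,32,0,0,0,0
spread_margarine,5,60,16,0.1,0.5,0,0,0,10,0,5,0
spread_butter,5,80,52,0.5,0.6,0,0,0,1,0,15,0
cooking_oil,10,99,8,0,0,0,0,0,0,0,0,0
cooking_butter,10,80,52,0.5,0.6,0,0,0,1,0,15,0
cooking_other,10,70,25,0.3,0.5,0,0,0,2,0,8,0
cream,15,20,13,2.5,4,0,0,0,0.2,0.5,80,0.05
dressing_oil,10,45,5,0.5,5,3,0,0,0,0,5,0.1
dressing_other,10,10,1.5,1,12,8,0.2,0,0,0,10,0.1
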