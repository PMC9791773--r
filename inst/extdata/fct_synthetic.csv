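food_item,component_id,energy_kcal_100g,vitamin_a_100g,iron_100g
rice_cooked,cereals,116,0,1.3
wheat_noodles,cereals,110,0,1.0
spinach,vegetables,28,487,2.9
cabbage,vegetables,24,13,0.8
apple,fruits,54,3,0.6
banana,fruits,93,10,0.4
whole_milk,dairy,54,24,0.3
yogurt,dairy,72,26,0.4
tofu,soybeans,82,0,1.9
carp,aquatic,109,25,1.3
egg_boiled,eggs,144,234,2.0
pork_lean,red_meat_poultry,143,44,3.0
chicken,red_meat_poultry,167,48,1.4
biscuit,snacks,433,50,1.6
candy,snacks,397,0,0.2
vegetable_oil,,899,0,0
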