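# dietbiome FPQ scoring configuration, version 1
# item_id: column name expected in the FPQ response table
# component: one of the 11 diet-score components
# daily_tier: times-per-month value assigned to response category 6
# inverse_scored: TRUE for red/processed meat items (category inverted first)
# fiber_source: TRUE for items entering the combined fiber sources score
item_id	component	daily_tier	inverse_scored	fiber_source	label
bread_rye	breads	60	FALSE	TRUE	Rye and crisp bread
bread_graham	breads	60	FALSE	TRUE	Graham and multi-grain bread
veg_fresh	vegetables	60	FALSE	TRUE	Fresh vegetables and root vegetables
veg_cooked	vegetables	45	FALSE	TRUE	Cooked vegetables and legumes
veg_dishes	vegetables	45	FALSE	TRUE	Vegetable dishes
fruits	fruits	60	FALSE	TRUE	Fruits
berries	berries	45	FALSE	TRUE	Fresh and frozen berries
juices	juices	45	FALSE	TRUE	Fruit and berry juices
fish	fish	45	FALSE	FALSE	Fish, fish products, and fish dishes
poultry	poultry	45	FALSE	FALSE	Poultry, poultry products, and poultry dishes
cheese_lowfat	low_fat_cheeses	60	FALSE	FALSE	Low-fat cheeses
dressings_oils	dressings_oils	45	FALSE	FALSE	Salad dressings and oils
nuts	nuts_seeds	45	FALSE	FALSE	Nuts
seeds	nuts_seeds	45	FALSE	FALSE	Seeds
meat_dishes	red_processed_meat	30	TRUE	FALSE	Meat dishes
sausages	red_processed_meat	30	TRUE	FALSE	Sausages
cold_cuts	red_processed_meat	45	TRUE	FALSE	Cold cuts
charcuterie	red_processed_meat	45	TRUE	FALSE	Charcuterie
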