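keyword,category_id
vegetable,other_vegetables
fruit,other_fruits
berries,other_fruits
nut,other_nuts
oil,other_oils
flour,other_grains
grain,other_grains
cereal,other_grains
bean,other_legumes
lentil,other_legumes
fish,other_fish
seafood,other_fish
milk,milk
cheese,cheese
syrup,glucose_syrup
spice,spices
herb,dried_herbs
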