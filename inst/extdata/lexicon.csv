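synonym,category_id
tomatoes,tomatoes
onions,onions
garlic,garlic
carrots,carrots
potatoes,potatoes
peas,peas
spinach,spinach
broccoli,broccoli
cauliflower,cauliflower
peppers,peppers
lettuce,lettuce
cucumber,cucumber
courgettes,courgettes
mushrooms,mushrooms
sweetcorn,sweetcorn
beetroot,beetroot
cabbage,cabbage
celery,celery
leeks,leeks
pumpkin,pumpkin
other vegetables,other_vegetables
apples,apples
bananas,bananas
oranges,oranges
lemons,lemons
strawberries,strawberries
raspberries,raspberries
blueberries,blueberries
grapes,grapes
pineapple,pineapple
mango,mango
peaches,peaches
pears,pears
cherries,cherries
dates,dates
raisins,raisins
coconut,coconut
olives,olives
other fruits,other_fruits
almonds,almonds
hazelnuts,hazelnuts
walnuts,walnuts
cashews,cashews
peanuts,peanuts
other nuts,other_nuts
olive oil,olive_oil
rapeseed oil,rapeseed_oil
sunflower oil,sunflower_oil
palm oil,palm_oil
coconut oil,coconut_oil
walnut oil,walnut_oil
other oils,other_oils
wheat flour,wheat_flour
rice,rice
oats,oats
maize,maize
barley,barley
rye,rye
buckwheat,buckwheat
quinoa,quinoa
spelt,spelt
other grains,other_grains
soybeans,soybeans
chickpeas,chickpeas
lentils,lentils
kidney beans,kidney_beans
soy protein,soy_protein
other legumes,other_legumes
beef,beef
lamb,lamb
pork,pork
chicken,chicken
turkey,turkey
duck,duck
salmon,salmon
tuna,tuna
cod,cod
prawns,prawns
haddock,haddock
mackerel,mackerel
other fish,other_fish
milk,milk
cheese,cheese
cream,cream
yogurt,yogurt
butter,butter
milk powder,milk_powder
whey powder,whey_powder
eggs,eggs
sugar,sugar
honey,honey
glucose syrup,glucose_syrup
cocoa powder,cocoa_powder
chocolate,chocolate
maple syrup,maple_syrup
molasses,molasses
coffee,coffee
tea,tea
yeast,yeast
vinegar,vinegar
dried herbs,dried_herbs
spices,spices
cornstarch,cornstarch
mustard,mustard
vanilla,vanilla
cinnamon,cinnamon
ginger,ginger
turmeric,turmeric
black pepper,black_pepper
water,water
salt,salt
tomato,tomatoes
tomato puree,tomatoes
onion,onions
carrot,carrots
potato,potatoes
pea,peas
red peppers,peppers
mushroom,mushrooms
apple,apples
banana,bananas
orange juice,oranges
lemon juice,lemons
strawberry,strawberries
sultanas,raisins
desiccated coconut,coconut
almond,almonds
hazelnut,hazelnuts
walnut,walnuts
peanut,peanuts
cashew nuts,cashews
extra virgin olive oil,olive_oil
vegetable oil,rapeseed_oil
plain flour,wheat_flour
flour,wheat_flour
wholemeal flour,wheat_flour
wheat semolina,wheat_flour
basmati rice,rice
rolled oats,oats
oatmeal,oats
maize flour,maize
cornflour,cornstarch
sweetcorn kernels,sweetcorn
soya beans,soybeans
soya protein,soy_protein
tofu,soybeans
red lentils,lentils
butter beans,kidney_beans
minced beef,beef
beef mince,beef
pork shoulder,pork
chicken breast,chicken
smoked salmon,salmon
tuna flakes,tuna
king prawns,prawns
whole milk,milk
skimmed milk,milk
semi skimmed milk,milk
cheddar cheese,cheese
mozzarella,cheese
parmesan,cheese
double cream,cream
greek yogurt,yogurt
yoghurt,yogurt
unsalted butter,butter
skimmed milk powder,milk_powder
free range eggs,eggs
egg,eggs
pasteurised egg,eggs
caster sugar,sugar
demerara sugar,sugar
brown sugar,sugar
golden syrup,glucose_syrup
invert sugar syrup,glucose_syrup
dark chocolate,chocolate
milk chocolate,chocolate
cocoa,cocoa_powder
sea salt,salt
spring water,water
mineral water,water
instant coffee,coffee
black tea,tea
white wine vinegar,vinegar
cider vinegar,vinegar
mixed herbs,dried_herbs
basil,dried_herbs
oregano,dried_herbs
paprika,spices
mixed spice,spices
vanilla extract,vanilla
ground cinnamon,cinnamon
pepper,black_pepper
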