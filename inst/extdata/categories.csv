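category_id,name,class,is_fish,aggregate,energy_kj,satfat_g,sugars_g,sodium_mg,protein_g,fiber_g,fvno,ghg_base,land_base,water_base,eutro_base
tomatoes,tomatoes,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
onions,onions,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
garlic,garlic,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
carrots,carrots,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
potatoes,potatoes,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
peas,peas,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
spinach,spinach,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
broccoli,broccoli,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
cauliflower,cauliflower,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
peppers,peppers,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
lettuce,lettuce,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
cucumber,cucumber,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
courgettes,courgettes,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
mushrooms,mushrooms,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
sweetcorn,sweetcorn,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
beetroot,beetroot,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
cabbage,cabbage,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
celery,celery,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
leeks,leeks,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
pumpkin,pumpkin,vegetable,FALSE,FALSE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
other_vegetables,other vegetables,vegetable,FALSE,TRUE,120,0.1,3,20,2,2.5,1,0.5,0.4,300,2
apples,apples,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
bananas,bananas,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
oranges,oranges,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
lemons,lemons,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
strawberries,strawberries,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
raspberries,raspberries,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
blueberries,blueberries,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
grapes,grapes,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
pineapple,pineapple,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
mango,mango,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
peaches,peaches,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
pears,pears,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
cherries,cherries,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
dates,dates,fruit,FALSE,FALSE,1180,0.1,63,5,0.8,8,1,0.7,0.9,800,2
raisins,raisins,fruit,FALSE,FALSE,1250,0.1,59,5,0.8,4,1,0.7,0.9,800,2
coconut,coconut,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
olives,olives,fruit,FALSE,FALSE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
other_fruits,other fruits,fruit,FALSE,TRUE,250,0.1,10,5,0.8,2,1,0.7,0.9,800,2
almonds,almonds,nut,FALSE,FALSE,2500,4,4,10,20,8,1,2.3,7,16000,8
hazelnuts,hazelnuts,nut,FALSE,FALSE,2500,4,4,10,20,8,1,2.5,8,4000,10
walnuts,walnuts,nut,FALSE,FALSE,2500,4,4,10,20,8,1,2.5,8,4000,10
cashews,cashews,nut,FALSE,FALSE,2500,4,4,10,20,8,1,2.5,8,4000,10
peanuts,peanuts,nut,FALSE,FALSE,2500,4,4,10,20,8,1,2.5,8,4000,10
other_nuts,other nuts,nut,FALSE,TRUE,2500,4,4,10,20,8,1,2.5,8,4000,10
olive_oil,olive oil,oil,FALSE,FALSE,3700,14,0,0,0,0,1,5.4,26,9000,37
rapeseed_oil,rapeseed oil,oil,FALSE,FALSE,3700,7,0,0,0,0,1,3.5,10,1500,15
sunflower_oil,sunflower oil,oil,FALSE,FALSE,3700,11,0,0,0,0,0,3.5,10,1500,15
palm_oil,palm oil,oil,FALSE,FALSE,3700,50,0,0,0,0,0,7.6,2.4,500,11
coconut_oil,coconut oil,oil,FALSE,FALSE,3700,87,0,0,0,0,0,3.5,10,1500,15
walnut_oil,walnut oil,oil,FALSE,FALSE,3700,9,0,0,0,0,1,3.5,10,1500,15
other_oils,other oils,oil,FALSE,TRUE,3700,12,0,0,0,0,0,3.5,10,1500,15
wheat_flour,wheat flour,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
rice,rice,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,4,2.8,5000,35
oats,oats,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
maize,maize,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
barley,barley,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
rye,rye,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
buckwheat,buckwheat,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
quinoa,quinoa,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
spelt,spelt,grain,FALSE,FALSE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
other_grains,other grains,grain,FALSE,TRUE,1450,0.3,1,5,10,7,0,1.3,2.5,1500,5
soybeans,soybeans,legume,FALSE,FALSE,1400,0.5,2,10,21,12,0,0.9,6,500,5
chickpeas,chickpeas,legume,FALSE,FALSE,1400,0.5,2,10,21,12,0,0.9,6,500,5
lentils,lentils,legume,FALSE,FALSE,1400,0.5,2,10,21,12,0,0.9,6,500,5
kidney_beans,kidney beans,legume,FALSE,FALSE,1400,0.5,2,10,21,12,0,0.9,6,500,5
soy_protein,soy protein,legume,FALSE,FALSE,1400,0.5,2,10,21,12,0,0.9,6,500,5
other_legumes,other legumes,legume,FALSE,TRUE,1400,0.5,2,10,21,12,0,0.9,6,500,5
beef,beef,meat,FALSE,FALSE,1050,6,0,70,26,0,0,60,170,1500,300
lamb,lamb,meat,FALSE,FALSE,1050,6,0,70,26,0,0,25,180,1800,100
pork,pork,meat,FALSE,FALSE,1050,6,0,70,26,0,0,7,11,1800,80
chicken,chicken,meat,FALSE,FALSE,700,1.3,0,70,23,0,0,6,7,600,50
turkey,turkey,meat,FALSE,FALSE,640,1,0,70,24,0,0,6.5,8,600,50
duck,duck,meat,FALSE,FALSE,1050,6,0,70,26,0,0,7,9,600,50
salmon,salmon,fish,TRUE,FALSE,800,1,0,90,20,0,0,8,4,2000,80
tuna,tuna,fish,TRUE,FALSE,800,1,0,90,20,0,0,8,4,2000,80
cod,cod,fish,TRUE,FALSE,800,1,0,90,20,0,0,8,4,2000,80
prawns,prawns,fish,TRUE,FALSE,800,1,0,90,20,0,0,14,3,3000,200
haddock,haddock,fish,TRUE,FALSE,800,1,0,90,20,0,0,8,4,2000,80
mackerel,mackerel,fish,TRUE,FALSE,800,1,0,90,20,0,0,8,4,2000,80
other_fish,other fish,fish,TRUE,TRUE,800,1,0,90,20,0,0,8,4,2000,80
milk,milk,dairy,FALSE,FALSE,270,1.1,4.7,44,3.4,0,0,3,9,700,10
cheese,cheese,dairy,FALSE,FALSE,1700,21,0.5,700,25,0,0,21,40,5000,100
cream,cream,dairy,FALSE,FALSE,1900,12,3,40,2.3,0,0,8,15,1500,30
yogurt,yogurt,dairy,FALSE,FALSE,330,1.7,5,60,4.3,0,0,3,9,700,10
butter,butter,dairy,FALSE,FALSE,3000,52,0.6,600,0.9,0,0,12,20,1000,50
milk_powder,milk powder,dairy,FALSE,FALSE,2050,16,38,370,26,0,0,20,60,4000,70
whey_powder,whey powder,dairy,FALSE,FALSE,1500,0.7,70,580,12,0,0,10,30,2000,40
eggs,eggs,egg,FALSE,FALSE,600,3.1,0.3,140,12.6,0,0,4.5,6,600,20
sugar,sugar,sugar,FALSE,FALSE,1700,0,100,1,0,0,0,1.8,2,600,5
honey,honey,sugar,FALSE,FALSE,1300,0,82,1,0,0,0,1.8,2,600,5
glucose_syrup,glucose syrup,sugar,FALSE,FALSE,1700,0,100,1,0,0,0,1.8,2,600,5
cocoa_powder,cocoa powder,sugar,FALSE,FALSE,1550,12,1,20,20,30,0,20,40,2500,80
chocolate,chocolate,sugar,FALSE,FALSE,2200,18,50,20,5,7,0,19,35,2000,70
maple_syrup,maple syrup,sugar,FALSE,FALSE,1700,0,100,1,0,0,0,1.8,2,600,5
molasses,molasses,sugar,FALSE,FALSE,1700,0,100,1,0,0,0,1.8,2,600,5
coffee,coffee,other,FALSE,FALSE,400,0.2,1,10,3,2,0,17,15,1000,50
tea,tea,other,FALSE,FALSE,400,0.2,1,10,3,2,0,6,6,800,10
yeast,yeast,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
vinegar,vinegar,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
dried_herbs,dried herbs,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
spices,spices,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
cornstarch,cornstarch,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
mustard,mustard,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
vanilla,vanilla,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
cinnamon,cinnamon,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
ginger,ginger,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
turmeric,turmeric,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
black_pepper,black pepper,other,FALSE,FALSE,400,0.2,1,10,3,2,0,1.5,2,500,4
water,water,water,FALSE,FALSE,0,0,0,0,0,0,0,0,0,0,0
salt,salt,salt,FALSE,FALSE,0,0,0,38758,0,0,0,0,0,0,0
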