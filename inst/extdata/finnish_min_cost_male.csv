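food,main_category,quantity_baseline_g,quantity_mincost_g,ghge_baseline_g,ghge_mincost_g,cost_baseline_eur,cost_mincost_eur
Beer and cider,Alcohol,127.0,0.0,200,0,0.61,0.00
Wine and spirit,Alcohol,19.2,0.0,0,0,0.23,0.00
Coffee,Beverages,495.0,0.0,200,0,0.22,0.00
Soft drink,Beverages,103.8,0.0,0,0,0.17,0.00
Tea,Beverages,81.1,0.0,0,0,0.01,0.00
Barley and barley products,Cereals,1.1,0.0,0,0,0.00,0.00
Cereal/seed/soy drinks,Cereals,7.7,0.0,0,0,0.03,0.00
Other grains,Cereals,2.2,0.0,0,0,0.01,0.00
Oat and oat products,Cereals,15.5,0.0,0,0,0.03,0.00
Rice,Cereals,10.3,0.0,0,0,0.02,0.00
Rye,Cereals,40.1,113.1,0,100,0.08,0.23
Starches,Cereals,2.3,0.0,0,0,0.01,0.00
Wheat,Cereals,78.4,245.6,100,300,0.06,0.19
"Sport foods, nutritional support",Diet products,1.7,0.0,0,0,0.06,0.00
Eggs,Eggs,24.2,0.3,100,0,0.08,0.00
Butter,Fats,4.9,0.0,100,0,0.02,0.00
Blended spread,Fats,13.6,0.0,100,0,0.08,0.00
Cooking and animal fat,Fats,5.1,0.0,0,0,0.02,0.00
Oils,Fats,10.3,24.9,0,100,0.06,0.14
Salad dressings,Fats,4.7,0.0,0,0,0.04,0.00
Margarines >= 55%,Fats,9.0,20.9,0,100,0.04,0.09
Margarines < 55%,Fats,5.1,0.0,0,0,0.02,0.00
"Fish, seafood",Fish,25.4,19.3,100,100,0.27,0.20
Fish products,Fish,10.3,0.0,0,0,0.18,0.00
Condiments,Flavoring,9.4,0.0,0,0,0.04,0.00
Dried spices and herbs,Flavoring,0.1,0.0,0,0,0.00,0.00
Malaceous fruit,Fruits,32.0,0.0,0,0,0.06,0.00
Berries,Fruits,24.2,0.0,0,0,0.09,0.00
Citrus fruit,Fruits,23.9,0.0,0,0,0.04,0.00
Juice drink,Fruits,75.8,0.0,100,0,0.32,0.00
Canned fruit,Fruits,4.3,0.0,0,0,0.02,0.00
Other fruits,Fruits,50.7,0.0,100,0,0.12,0.00
"Juices, including vegetable juices",Fruits,49.7,0.0,100,0,0.08,0.00
Miscellaneous ingredients,Ingredients,6.6,0.0,0,0,0.04,0.00
Salt,Ingredients,4.2,1.5,0,0,0.01,0.00
Sweeteners,Ingredients,0.0,0.0,0,0,0.00,0.00
Nuts and seeds,Legumes and nuts,6.7,0.0,0,0,0.09,0.00
Pulse vegetables and products,Legumes and nuts,9.6,0.0,0,0,0.04,0.00
Soya products,Legumes and nuts,2.7,0.0,0,0,0.01,0.00
Beef and lamb/mutton,Meat,35.6,0.0,1100,0,0.37,0.00
"Cold cuts, meat products",Meat,24.1,0.0,400,0,0.26,0.00
Offal,Meat,2.4,12.3,0,200,0.02,0.10
Pork and game,Meat,40.9,0.0,300,0,0.34,0.00
Poultry,Meat,42.8,0.0,200,0,0.20,0.00
Sausages,Meat,28.1,0.0,200,0,0.17,0.00
"Cold cuts, sausages",Meat,7.3,0.0,100,0,0.07,0.00
Ripened/processed cheese >17%,Dairy,26.9,0.0,400,0,0.24,0.00
Ripened/processed cheese <=17%,Dairy,6.5,0.0,100,0,0.06,0.00
Unripened/fresh cheese >15%,Dairy,4.1,0.0,0,0,0.04,0.00
Unripened/fresh cheese <=15%,Dairy,6.9,0.0,0,0,0.06,0.00
Cream,Dairy,16.2,0.0,0,0,0.08,0.00
Quark,Dairy,20.9,0.0,0,0,0.18,0.00
Ice cream,Dairy,9.8,0.0,0,0,0.05,0.00
Skimmed milk,Dairy,102.7,117.8,100,100,0.11,0.13
Milk with >2% fat,Dairy,25.4,405.0,0,400,0.02,0.34
Milk powders,Dairy,0.6,0.0,0,0,0.01,0.00
Milk with <=2% fat,Dairy,174.4,0.0,200,0,0.20,0.00
Soured/cultured milk,Dairy,29.5,0.0,0,0,0.05,0.00
"Fermented milk products, other",Dairy,3.7,0.0,0,0,0.02,0.00
Yogurt,Dairy,50.5,0.0,100,0,0.12,0.00
Potato products,Potatoes,12.9,0.0,0,0,0.05,0.00
Potato,Potatoes,71.7,394.8,0,0,0.06,0.33
Chocolate,Sugar,6.6,0.0,0,0,0.10,0.00
Jam,Sugar,5.0,0.0,0,0,0.03,0.00
Sugar and syrups,Sugar,14.4,0.0,0,0,0.03,0.00
Nonchocolate confectionery,Sugar,6.2,0.0,0,0,0.09,0.00
Cabbage,Vegetables,13.6,59.2,0,0,0.03,0.14
Edible fungi,Vegetables,3.6,0.0,0,0,0.02,0.00
Root vegetables and tubers,Vegetables,28.3,0.0,0,0,0.06,0.00
Canned vegetables,Vegetables,19.0,0.0,0,0,0.08,0.00
Fruit vegetables,Vegetables,75.8,0.0,200,0,0.20,0.00
Leaf vegetables,Vegetables,21.6,0.0,0,0,0.17,0.00
Onion-family vegetables,Vegetables,14.7,0.0,0,0,0.02,0.00
All,Total,2350.4,1414.8,5296.5,1452.1,6.90,1.88
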