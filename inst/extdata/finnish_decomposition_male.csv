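main_category,metric,scenario,intra,inter
Alcohol,cost,health_only,0.02,-0.16
Beverages,cost,health_only,-0.02,-0.01
Cereals,cost,health_only,0.00,0.15
Diet products,cost,health_only,0.00,0.00
Eggs,cost,health_only,0.00,-0.01
Fats,cost,health_only,-0.01,-0.03
Fish,cost,health_only,0.00,0.01
Flavoring,cost,health_only,0.00,0.00
Fruits,cost,health_only,-0.01,0.06
Ingredients,cost,health_only,0.01,0.00
Legumes,cost,health_only,0.00,0.04
Meat,cost,health_only,-0.04,-0.50
Milk,cost,health_only,-0.11,-0.40
Potatoes,cost,health_only,0.00,0.01
Sugars,cost,health_only,0.00,-0.04
Vegetables,cost,health_only,-0.02,0.18
Total,cost,health_only,-0.18,-0.69
Alcohol,cost,health_ghge_minus33,0.02,-0.16
Beverages,cost,health_ghge_minus33,-0.03,-0.02
Cereals,cost,health_ghge_minus33,0.00,0.15
Diet products,cost,health_ghge_minus33,0.00,0.00
Eggs,cost,health_ghge_minus33,0.00,-0.01
Fats,cost,health_ghge_minus33,-0.01,-0.02
Fish,cost,health_ghge_minus33,0.00,0.00
Flavoring,cost,health_ghge_minus33,0.00,0.00
Fruits,cost,health_ghge_minus33,-0.01,0.05
Ingredients,cost,health_ghge_minus33,0.01,0.00
Legumes,cost,health_ghge_minus33,0.00,0.04
Meat,cost,health_ghge_minus33,-0.08,-0.57
Milk,cost,health_ghge_minus33,-0.10,-0.40
Potatoes,cost,health_ghge_minus33,0.00,0.01
Sugars,cost,health_ghge_minus33,0.00,-0.03
Vegetables,cost,health_ghge_minus33,-0.02,0.16
Total,cost,health_ghge_minus33,-0.23,-0.79
Alcohol,cost,health_ghge_minus50,0.10,-0.41
Beverages,cost,health_ghge_minus50,-0.09,-0.05
Cereals,cost,health_ghge_minus50,-0.01,0.18
Diet products,cost,health_ghge_minus50,0.00,0.00
Eggs,cost,health_ghge_minus50,0.00,0.00
Fats,cost,health_ghge_minus50,0.00,-0.01
Fish,cost,health_ghge_minus50,0.01,-0.09
Flavoring,cost,health_ghge_minus50,0.00,0.00
Fruits,cost,health_ghge_minus50,-0.03,-0.03
Ingredients,cost,health_ghge_minus50,0.00,0.00
Legumes,cost,health_ghge_minus50,0.01,0.03
Meat,cost,health_ghge_minus50,-0.19,-0.91
Milk,cost,health_ghge_minus50,-0.17,-0.31
Potatoes,cost,health_ghge_minus50,0.00,0.03
Sugars,cost,health_ghge_minus50,0.00,-0.01
Vegetables,cost,health_ghge_minus50,-0.01,0.00
Total,cost,health_ghge_minus50,-0.39,-1.58
Alcohol,ghge,health_only,0.00,-0.04
Beverages,ghge,health_only,-0.01,-0.01
Cereals,ghge,health_only,-0.01,0.12
Diet products,ghge,health_only,0.00,0.00
Eggs,ghge,health_only,0.00,-0.01
Fats,ghge,health_only,-0.09,-0.02
Fish,ghge,health_only,0.00,0.00
Flavoring,ghge,health_only,0.00,0.00
Fruits,ghge,health_only,0.00,0.02
Ingredients,ghge,health_only,0.00,0.00
Legumes,ghge,health_only,0.00,0.01
Meat,ghge,health_only,-0.11,-0.81
Milk,ghge,health_only,-0.28,-0.27
Potatoes,ghge,health_only,0.00,0.00
Sugars,ghge,health_only,0.00,-0.02
Vegetables,ghge,health_only,0.00,0.08
Total,ghge,health_only,-0.51,-0.92
Alcohol,ghge,health_ghge_minus33,0.00,-0.04
Beverages,ghge,health_ghge_minus33,-0.02,-0.01
Cereals,ghge,health_ghge_minus33,-0.01,0.13
Diet products,ghge,health_ghge_minus33,0.00,0.00
Eggs,ghge,health_ghge_minus33,0.00,0.00
Fats,ghge,health_ghge_minus33,-0.08,-0.02
Fish,ghge,health_ghge_minus33,0.00,0.00
Flavoring,ghge,health_ghge_minus33,0.00,0.00
Fruits,ghge,health_ghge_minus33,0.00,0.02
Ingredients,ghge,health_ghge_minus33,0.00,0.00
Legumes,ghge,health_ghge_minus33,0.00,0.01
Meat,ghge,health_ghge_minus33,-0.41,-0.83
Milk,ghge,health_ghge_minus33,-0.28,-0.27
Potatoes,ghge,health_ghge_minus33,0.00,0.00
Sugars,ghge,health_ghge_minus33,0.00,-0.01
Vegetables,ghge,health_ghge_minus33,-0.01,0.07
Total,ghge,health_ghge_minus33,-0.81,-0.96
Alcohol,ghge,health_ghge_minus50,0.00,-0.09
Beverages,ghge,health_ghge_minus50,-0.09,-0.03
Cereals,ghge,health_ghge_minus50,-0.01,0.16
Diet products,ghge,health_ghge_minus50,0.00,0.00
Eggs,ghge,health_ghge_minus50,0.00,0.00
Fats,ghge,health_ghge_minus50,-0.08,-0.01
Fish,ghge,health_ghge_minus50,0.00,-0.03
Flavoring,ghge,health_ghge_minus50,0.00,0.00
Fruits,ghge,health_ghge_minus50,-0.01,-0.01
Ingredients,ghge,health_ghge_minus50,0.00,0.00
Legumes,ghge,health_ghge_minus50,0.00,0.01
Meat,ghge,health_ghge_minus50,-0.56,-1.32
Milk,ghge,health_ghge_minus50,-0.34,-0.20
Potatoes,ghge,health_ghge_minus50,0.00,0.00
Sugars,ghge,health_ghge_minus50,0.00,-0.01
Vegetables,ghge,health_ghge_minus50,-0.03,0.00
Total,ghge,health_ghge_minus50,-1.13,-1.51
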