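category,group,serving_amount,serving_unit,wholegrain_flag,is_beverage,manual_only
vegetables,vegetables,80,g,FALSE,FALSE,FALSE
fruits,fruit,80,g,FALSE,FALSE,FALSE
nuts,nuts,25,g,FALSE,FALSE,FALSE
legumes/pulses,legumes,120,g,FALSE,FALSE,FALSE
bread white,cereals,50,g,FALSE,FALSE,FALSE
bread non-white,cereals,50,g,TRUE,FALSE,FALSE
pasta white,cereals,50,g,FALSE,FALSE,FALSE
pasta non-white,cereals,50,g,TRUE,FALSE,FALSE
rice white,cereals,50,g,FALSE,FALSE,FALSE
rice non-white,cereals,50,g,TRUE,FALSE,FALSE
cereals unprocessed,cereals,50,g,TRUE,FALSE,FALSE
cereals processed,cereals,50,g,FALSE,FALSE,FALSE
potatoes non-fried,potatoes,200,g,FALSE,FALSE,FALSE
French fries,potatoes,200,g,FALSE,FALSE,FALSE
meat white,white_meat,120,g,FALSE,FALSE,FALSE
meat red,red_meat,120,g,FALSE,FALSE,FALSE
fish/seafood,fish,120,g,FALSE,FALSE,FALSE
eggs,eggs,120,g,FALSE,FALSE,FALSE
breaded food,,120,g,FALSE,FALSE,FALSE
sweets,sweets,20,g,FALSE,FALSE,FALSE
milk,dairy,200,mL,FALSE,FALSE,FALSE
yogurt,dairy,135,g,FALSE,FALSE,FALSE
cheese,dairy,30,g,FALSE,FALSE,FALSE
beverage—water,,200,mL,FALSE,TRUE,FALSE
beverage—coffee,,150,mL,FALSE,TRUE,FALSE
beverage—tea,,200,mL,FALSE,TRUE,FALSE
beverage—wine,fermented_beverages,100,mL,FALSE,TRUE,FALSE
beverage—beer,fermented_beverages,250,mL,FALSE,TRUE,FALSE
beverage—alcoholic,,40,mL,FALSE,TRUE,FALSE
beverage—soft-drink,sweets,330,mL,FALSE,TRUE,FALSE
beverage—milky coffee,,200,mL,FALSE,TRUE,FALSE
olive oil,olive_oil,10,g,FALSE,FALSE,TRUE
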