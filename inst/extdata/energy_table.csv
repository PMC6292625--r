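product,activity,energy_kcal_per_kg,price_per_kg
banana,crop,890,250
sorghum,crop,3390,600
maize,crop,3560,500
cassava,crop,1600,300
beans,crop,3410,1500
coffee,crop,0,3500
other_crop,crop,2500,700
cattle,livestock,1500,4000
poultry,livestock,1650,6000
other_livestock,livestock,600,1200
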