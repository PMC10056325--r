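# Synthetic DIS component registry (19 groups: 18 whole foods/beverages plus
# one composite micronutrient supplement group). Weights and standardization
# means/SDs are ILLUSTRATIVE SYNTHETIC values with literature-consistent
# signs (pro-inflammatory > 0); the published component weights belong to the
# cited validation study and are not reproduced here. Users can substitute
# their own file with the same columns.
# Columns: name, weight (dimensionless), mean and sd of intake (amount/day)
# used for component standardization.
name,weight,mean,sd
leafy_greens_cruciferous,-0.14,45.0,30.0
tomatoes,-0.78,60.0,40.0
apples_berries,-0.65,55.0,45.0
deep_yellow_vegetables,-0.57,25.0,20.0
other_fruits_juices,-1.02,190.0,130.0
other_vegetables,-0.27,80.0,50.0
legumes,-0.12,25.0,20.0
fish,-0.08,35.0,25.0
poultry,-0.45,30.0,22.0
red_meat,0.02,55.0,35.0
processed_meat,0.68,20.0,16.0
added_sugars,0.56,35.0,25.0
high_fat_dairy,0.51,90.0,60.0
low_fat_dairy,-0.12,70.0,65.0
coffee_tea,-0.25,400.0,250.0
nuts,-0.44,8.0,9.0
other_fats,0.31,20.0,13.0
refined_grains,0.72,180.0,80.0
supplements,-0.80,0.25,0.43
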