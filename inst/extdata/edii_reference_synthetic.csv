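# Synthetic E-DII reference registry (34 food parameters).
# These reference means/SDs and inflammatory effect scores are ILLUSTRATIVE
# SYNTHETIC values on realistic scales with literature-consistent signs
# (pro-inflammatory > 0, anti-inflammatory < 0). The real global comparative
# database and effect scores are proprietary and are not shipped here; users
# with access can substitute their own file with the same columns.
# Columns: name, unit (amount/day), global_mean and global_sd on the raw
# scale, energy_adjusted_mean and energy_adjusted_sd per 1000 kcal,
# effect_score (dimensionless).
name,unit,global_mean,global_sd,energy_adjusted_mean,energy_adjusted_sd,effect_score
carbohydrate,g,272.0,40.0,136.0,22.0,0.10
protein,g,79.4,13.9,39.7,7.6,0.02
total_fat,g,71.4,19.4,35.7,9.7,0.30
alcohol,g,14.0,3.7,7.0,1.9,-0.28
fiber,g,18.8,4.9,9.4,2.5,-0.66
cholesterol,mg,279.4,51.2,139.7,25.6,0.11
saturated_fat,g,28.6,8.0,14.3,4.0,0.37
mufa,g,27.0,6.1,13.5,3.1,-0.01
pufa,g,13.9,3.8,7.0,1.9,-0.34
omega3,g,1.06,1.06,0.53,0.53,-0.44
omega6,g,10.8,7.5,5.4,3.8,-0.16
niacin,mg,25.9,11.8,13.0,5.9,-0.25
thiamin,mg,1.70,0.66,0.85,0.33,-0.10
riboflavin,mg,1.70,0.79,0.85,0.40,-0.07
vitamin_b12,ug,5.15,2.70,2.58,1.35,0.11
vitamin_b6,mg,1.47,0.74,0.74,0.37,-0.37
iron,mg,13.4,3.7,6.7,1.9,0.03
magnesium,mg,310.0,139.0,155.0,70.0,-0.48
zinc,mg,9.8,2.2,4.9,1.1,-0.31
vitamin_a,ug,984.0,519.0,492.0,260.0,-0.40
vitamin_c,mg,118.0,43.5,59.0,21.8,-0.42
vitamin_d,ug,6.26,2.21,3.13,1.11,-0.45
vitamin_e,mg,8.73,1.49,4.37,0.75,-0.42
folic_acid,ug,273.0,70.7,136.5,35.4,-0.19
beta_carotene,ug,3718.0,1720.0,1859.0,860.0,-0.58
anthocyanidins,mg,18.1,21.1,9.0,10.6,-0.13
flavan3ols,mg,95.8,85.9,47.9,43.0,-0.42
flavones,mg,1.55,0.07,0.78,0.04,-0.62
flavonols,mg,17.7,6.8,8.9,3.4,-0.47
flavanones,mg,11.7,3.8,5.9,1.9,-0.25
isoflavones,mg,1.24,0.20,0.62,0.10,-0.59
garlic,g,4.35,2.90,2.18,1.45,-0.41
onion,g,35.9,18.4,18.0,9.2,-0.30
tea,g,1.69,1.53,0.85,0.77,-0.54
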