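attribute,modality,CD1,CD5,CD7,SD1,SD5,SD7
umami,taste,5.73,5.32,4.19,7.34,7.59,7.27
flavor_intensity,flavor,7.47,7.62,7.75,9.17,8.77,9.02
buttery,flavor,5.33,5.68,4.05,6.89,6.79,6.79
salty_aftertaste,aftertaste,4.20,4.30,3.57,3.63,3.48,3.22
mouth_drying,mouthfeel,5.82,5.94,6.27,4.49,4.48,4.77
mouthwatering,mouthfeel,6.90,6.92,6.09,7.71,7.44,8.07
odor_intensity,odor,8.31,8.30,9.71,7.61,9.20,9.28
marine_odor,odor,7.12,6.27,5.72,6.59,6.80,5.81
crustacean_odor,odor,7.93,7.57,5.82,6.58,7.45,6.69
mussels_odor,odor,4.81,5.80,6.30,5.51,6.16,6.18
fishy_off_odor,odor,3.82,4.06,6.78,3.24,4.89,6.32
fermented_odor,odor,3.18,4.59,7.02,2.45,3.91,6.06
lactic_sour_odor,odor,3.77,5.36,6.60,3.70,4.53,6.13
boiled_potato_flavor,flavor,6.10,5.79,4.10,6.21,6.02,4.63
fermented_flavor,flavor,2.06,3.24,5.32,2.69,2.67,4.16
boiled_potato_odor,odor,7.39,6.21,4.69,5.80,5.11,4.91
sweet_taste,taste,6.83,5.89,5.16,9.50,8.72,8.33
bitter_taste,taste,4.16,5.02,6.19,3.14,3.51,4.25
grilled_flavor,flavor,6.32,6.35,4.32,8.15,7.42,7.21
lactic_acid_flavor,flavor,3.46,4.72,5.86,3.16,3.75,4.72
pasty_texture,texture,6.09,5.95,5.56,5.57,4.32,3.90
sweet_aftertaste,aftertaste,5.88,4.16,3.90,8.15,7.56,7.27
sour_aftertaste,aftertaste,3.39,4.21,4.87,3.35,2.83,3.74
bitter_aftertaste,aftertaste,3.27,3.91,4.90,2.64,2.66,3.50
metallic_mouthfeel,mouthfeel,5.67,6.09,7.66,4.78,5.12,5.68
color_intensity,appearance,5.52,5.80,7.88,5.19,8.02,6.87
compactness,appearance,9.03,9.73,9.84,9.56,8.21,8.10
flakiness,appearance,7.10,5.27,5.99,5.83,6.41,6.94
sour_taste,taste,4.78,5.62,7.63,4.14,4.46,4.80
metallic_mussels_flavor,flavor,5.68,6.66,7.73,5.29,5.21,5.11
juicy_texture,texture,7.30,8.89,8.01,9.68,8.99,9.58
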