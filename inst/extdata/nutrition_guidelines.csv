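mode,nutrient,weight_class,day_lo,day_hi,recommended
EN,energy_kcal_per_kg,le_2500g,1,2,50
EN,energy_kcal_per_kg,le_2500g,3,6,90
EN,energy_kcal_per_kg,le_2500g,7,13,110
EN,energy_kcal_per_kg,le_2500g,14,Inf,120
EN,energy_kcal_per_kg,gt_2500g,1,2,55
EN,energy_kcal_per_kg,gt_2500g,3,6,95
EN,energy_kcal_per_kg,gt_2500g,7,13,110
EN,energy_kcal_per_kg,gt_2500g,14,Inf,115
PN,energy_kcal_per_kg,le_2500g,1,2,45
PN,energy_kcal_per_kg,le_2500g,3,6,75
PN,energy_kcal_per_kg,le_2500g,7,13,90
PN,energy_kcal_per_kg,le_2500g,14,Inf,95
PN,energy_kcal_per_kg,gt_2500g,1,2,40
PN,energy_kcal_per_kg,gt_2500g,3,6,70
PN,energy_kcal_per_kg,gt_2500g,7,13,85
PN,energy_kcal_per_kg,gt_2500g,14,Inf,90
EN,protein_g_per_kg,le_2500g,1,2,1.5
EN,protein_g_per_kg,le_2500g,3,6,2.5
EN,protein_g_per_kg,le_2500g,7,Inf,3.5
EN,protein_g_per_kg,gt_2500g,1,2,1.2
EN,protein_g_per_kg,gt_2500g,3,6,2.0
EN,protein_g_per_kg,gt_2500g,7,Inf,2.5
PN,protein_g_per_kg,le_2500g,1,2,2.0
PN,protein_g_per_kg,le_2500g,3,6,3.0
PN,protein_g_per_kg,le_2500g,7,Inf,3.5
PN,protein_g_per_kg,gt_2500g,1,2,1.5
PN,protein_g_per_kg,gt_2500g,3,6,2.5
PN,protein_g_per_kg,gt_2500g,7,Inf,3.0
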