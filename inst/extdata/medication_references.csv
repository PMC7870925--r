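drug,dose_per_kg,frequency_per_day,is_supplement
amikacin,15,1,FALSE
gentamicin,4,1,FALSE
ampicillin,50,2,FALSE
cefotaxime,50,2,FALSE
vancomycin,15,3,FALSE
meropenem,20,3,FALSE
caffeine_citrate,5,1,FALSE
phenobarbital,5,1,FALSE
fluconazole,6,1,FALSE
vitamin_d,1,1,TRUE
iron,2,1,TRUE
multivitamin,1,1,TRUE
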