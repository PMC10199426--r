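disease,n_acceptable,n_studies_reported,flag
Achalasia,18,27,
Behcet's disease,0,21,
Creutzfeldt-Jakob disease,0,5,
Fournier's gangrene,2,5,
Guillain-Barre syndrome,1,6,
Atypical hemolytic uremic syndrome,0,6,
Palmoplantar pustulosis,4,8,suspect: reported denominator 8 disagrees with the 5 studies tabulated for this disease
Prader-Willi syndrome,0,8,
Systemic lupus erythematosus,13,22,
Systemic sclerosis,12,28,
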