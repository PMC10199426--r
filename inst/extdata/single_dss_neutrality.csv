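disease,n_studies,most_neutrality,most_sensitivity,most_specificity,least_neutrality,least_sensitivity,least_specificity,flag
Achalasia,27,2.00,1.00,1.00,0.86,0.00,0.86,
Behcet's disease,21,1.10,0.10,1.00,0.61,0.00,0.61,
Creutzfeldt-Jakob disease,5,0.87,0.12,0.75,0.75,0.00,0.75,
Fournier's gangrene,5,2.00,1.00,1.00,0.45,0.00,0.45,
Guillain-Barre syndrome,6,1.80,0.91,0.89,0.33,0.00,0.33,
Atypical hemolytic uremic syndrome,6,0.71,0.08,0.62,0.44,0.00,0.44,
Palmoplantar pustulosis,5,2.00,1.00,1.00,0.00,0.00,0.00,
Prader-Willi syndrome,8,1.02,0.11,0.91,0.49,0.04,0.45,
Systemic lupus erythematosus,22,2.00,1.00,1.00,0.83,0.04,0.79,
Systemic sclerosis,28,2.00,1.00,1.00,0.82,0.00,0.82,
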