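disease,scale_name,n_indicators
Achalasia,Eckardt Score,40
Behcet's syndrome,Krause's Behcet's Disease Activity Assessment,38
Creutzfeldt-Jakob disease,Creutzfeldt-Jakob Disease Neurological Status Scale,29
Fournier's gangrene,Fournier's Gangrene Severity Index,20
Guillain-Barre syndrome,Guillain-Barre Rating Scale,20
Atypical hemolytic uremic syndrome,Pediatric Neurologic Assessment Score for Hemolytic Uremic Syndrome,28
Palmoplantar psoriasis,Palmoplantar Psoriasis Area and Severity Index,3
Prader-Willi syndrome,Prader-Willi Syndrome Behavioral Questionnaire,39
Systemic lupus erythematosus,Lupus Severity Index,48
Systemic sclerosis,Modified Rodnan Skin Score,38
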