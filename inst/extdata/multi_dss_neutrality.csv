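disease,n_studies,first_neutrality,first_sensitivity,first_specificity,composite_neutrality,composite_sensitivity,composite_specificity,flag
Acromegaly,30,0.899,0.029,0.870,1.034,0.110,0.923,
Amyotrophic lateral sclerosis,81,1.044,0.109,0.935,1.138,0.166,0.972,
Charcot Marie Tooth disease,12,1.371,0.472,0.898,1.117,0.215,0.902,
Cystic fibrosis,156,0.991,0.008,0.983,1.013,0.026,0.987,
Encephalitis,12,0.956,0.000,0.956,0.905,0.000,0.905,
Fabry disease,15,0.935,0.039,0.896,1.018,0.105,0.913,
Friedreich ataxia,18,1.102,0.299,0.803,1.248,0.344,0.904,
Gaucher disease type I,15,0.969,0.142,0.851,0.943,0.112,0.831,suspect: printed first-scale components 0.142 + 0.851 disagree with printed mean 0.969
Huntington's disease,32,1.456,0.500,0.956,1.162,0.205,0.957,
Juvenile rheumatoid arthritis,39,0.983,0.032,0.951,1.109,0.147,0.962,
Sjogren's syndrome,37,1.323,0.401,0.922,1.146,0.224,0.922,
Tourette syndrome,36,1.784,0.837,0.946,1.395,0.448,0.946,
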