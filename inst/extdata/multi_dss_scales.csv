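disease,first_scale,first_year,first_n_indicators,composite_members,composite_n_total,composite_duplicates_excluded,flag
Acromegaly,Clinical Activity Score of Acromegaly,1992,17,Clinical Activity Score of Acromegaly (1992); Acroscore (2015); ACRODAT (2017),3,26,suspect: composite total smaller than first scale
Amyotrophic lateral sclerosis,Appel ALS Rating Scale,1987,20,Appel ALS Rating Scale (1987); Amyotrophic Lateral Sclerosis Severity Score (1989); Modified Norris Scale (1996); Amyotrophic Lateral Sclerosis Functional Rating Scale (1999); Amyotrophic Lateral Sclerosis Utility Index (2005); Japan ALS Severity Classification (2012),71,7,
Charcot Marie Tooth disease,Charcot-Marie-Tooth Neuropathy Score,2007,9,Charcot-Marie-Tooth Neuropathy Score (2007); CMT Neuropathy Score (2011); CMT Examination Score (2011); CMT Pediatric Scale (2012); Mobility-Disability Severity Index (2014),16,26,
Cystic fibrosis,The Shwachman-Kulczycki Score,1958,20,The Shwachman-Kulczycki Score (1958); Brasfield Score (1979); Cystic Fibrosis Clinical Score (1999); Matouk Clinical Score (2004); Chrispin-Norman Score (2005),61,10,
Encephalitis,The Status Epilepticus Severity Score,2008,4,The Status Epilepticus Severity Score (2008); END IT Score (2016); The Epidemiology-Based Mortality Score in Status Epilepticus (2015); The Clinical Assessment Scale in Autoimmune Encephalitis (2019),43,2,
Fabry disease,The Mainz Severity Score Index,2003,25,The Mainz Severity Score Index (2003); FD Severity Scoring System (2009),37,0,
Friedreich ataxia,The International Cooperative Ataxia Rating Scale,1997,24,The International Cooperative Ataxia Rating Scale (1997); The Scale for the Assessment and Rating of Ataxia (2004); Friedreich Ataxia Rating Scale (2010),50,6,
Gaucher disease type I,Gaucher Disease Severity Score Index - Type I,2008,15,Gaucher Disease Severity Score Index - Type I (2008); The Disease Severity Scoring System (2015),1,25,suspect: composite total smaller than first scale
Huntington's disease,The Unified Huntington's Disease Rating Scale Motor Score,2013,7,The Unified Huntington's Disease Rating Scale Motor Score (2013); Problem Behaviors Assessment for Huntington Disease (2015),18,0,
Juvenile rheumatoid arthritis,Clinical Disease Activity Index for RA,2005,4,Clinical Disease Activity Index for RA (2005); Juvenile Arthritis Disease Activity Score (2009),8,0,
Sjogren's syndrome,EULAR Sjogren's Syndrome Disease Activity Index,2010,6,EULAR Sjogren's Syndrome Disease Activity Index (2010); The Sjogren's International Collaborative Clinical Alliance Ocular Staining Score (2015),11,0,
Tourette syndrome,Yale Global Tic Severity Scale,1977,15,Yale Global Tic Severity Scale (1977); The Shapiro Tourette Syndrome Severity Scale Score (2004); Premonitory Urge for Tic Disorders Scale (2012),28,0,
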