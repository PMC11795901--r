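# miniature synthetic MeSH descriptor list for tests and examples
Neoplasms
Humans
Breast Neoplasms
Female
Male
Adult
Aged
Middle Aged
Child
Animals
Mice
Risk Factors
Prognosis
Treatment Outcome
Quality of Life
Decision Making
Mass Screening
Early Detection of Cancer
Mammography
Biomarkers, Tumor
Antineoplastic Agents
Randomized Controlled Trials as Topic
Systematic Reviews as Topic
Sensitivity and Specificity
Surveys and Questionnaires
Cohort Studies
Case-Control Studies
Incidence
Prevalence
Survival Analysis
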