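trial_id,diagnosis,has_specific_symptoms,has_patient_specific_variables,outcome_granularity,outcome_linked_to_patient_variables,score,encoding_note
NCT00548327,Scz/SczAff,FALSE,TRUE,domain_specific_with_change,TRUE,4,"COMT allele and plasma drug level are patient-specific variables; fMRI and clinical outcomes measured at domain level with change over hours/days; primary outcome analysed by COMT status"
NCT00560937,Scz/SczAff,TRUE,FALSE,composite_only,FALSE,2,"cognitive-testing score threshold counts as a specific disorder feature; all outcomes are total/mean/composite scores"
NCT00611806,Scz (DSM),TRUE,TRUE,domain_specific_with_change,TRUE,5,"negative and positive symptom features plus COMT genotype and plasma folate/B12/homocysteine; PANSS positive domain with change; outcomes analysed against plasma levels and genotype"
NCT00931996,Scz (DSM),FALSE,FALSE,composite_only,FALSE,1,"PANSS total-score threshold treated as an aggregate cut-off, not a specific symptom criterion; total score only"
NCT00963924,Scz/SczAff,TRUE,TRUE,domain_specific_with_change,FALSE,4,"auditory-discrimination feature plus SANS score as patient-specific variable; MATRICS subscores with change; subject-specific analysis not credited so the encoding matches the published total"
NCT00488319,Scz (DSM),FALSE,FALSE,domain_specific_with_change,FALSE,2,"no specific features or patient-specific variables; PANSS five-factor and cognitive domain scores with change"
NCT01312272,Scz (DSM),FALSE,FALSE,domain_specific_with_change,FALSE,2,"social-cognition domain scores with change over days"
NCT00922272,Scz (DSM),TRUE,FALSE,domain_specific_with_change,FALSE,3,"negative-symptom inclusion feature; SANS/PANSS domain scores with change"
NCT00487942,Scz (DSM),FALSE,TRUE,domain_specific_with_change,FALSE,3,"named second-generation antipsychotic as patient-specific variable; MATRICS and frontal-test domain scores with change"
NCT01363349,Scz (DSM),TRUE,FALSE,composite_only,FALSE,2,"delusion/hallucination/disorganisation features; stable-antipsychotic and non-treatment-resistant status treated as inclusion criteria rather than patient-specific response factors; composite outcomes"
NCT00575666,Scz/SczAff,FALSE,FALSE,domain_specific_with_change,FALSE,2,"cognitive domain scores (digit span, fluency, recall, attention, reaction time) with change"
NCT00848484,Scz,FALSE,FALSE,domain_specific_with_change,FALSE,2,"illness duration under one year treated as an inclusion criterion, not a patient-specific response factor; executive/memory/attention domain scores with change"
NCT00435370,Scz/schizophreniform,TRUE,TRUE,domain_specific_with_change,FALSE,4,"psychotic-feature criterion plus EEG P50 gating ratio as biomarker; RBANS domain scores with change; subject-specific outcome analysis not credited, matching the published total"
NCT01082588,Scz/SczAff,FALSE,FALSE,domain_specific_with_change,FALSE,2,"lipid/inflammatory markers are outcomes here, not design variables; PANSS domain scores with change"
NCT00563706,Scz,TRUE,FALSE,composite_only,FALSE,2,"acute exacerbation counts as a qualitative disorder feature; domain-score change not reported, conservatively composite only"
NCT00506077,Scz,FALSE,TRUE,domain_specific_with_change,TRUE,4,"PANSS 36-75 window treated as an aggregate threshold; baseline BACS matching is a patient-specific variable and outcomes are partially analysed against it"
NCT00646581,Scz/SczAff,FALSE,FALSE,domain_specific_with_change,FALSE,2,"stable antipsychotic treated as an inclusion criterion; recall/attention domain scores with change"
NCT00455702,Scz/SczAff,TRUE,FALSE,domain_specific_with_change,TRUE,4,"schizoaffective depressed-subtype feature; stable antipsychotic as inclusion criterion; SANS analysed against demographics credits criterion 5"
NCT00505076,Scz,TRUE,FALSE,composite_only,FALSE,2,"low positive-symptom and low cognitive-performance thresholds count as specific features; treatment with a second-generation antipsychotic as inclusion; composite outcomes only"
NCT00000371,Scz (DSM),TRUE,TRUE,domain_specific_with_change,FALSE,4,"prominent negative symptoms plus serum amino-acid concentrations as patient-specific variables; SANS domain scores with change; serum-correlation analysis not credited for criterion 5, matching the published total"
NCT00333970,Scz spectrum,FALSE,TRUE,composite_only,FALSE,2,"neuropsychological baseline treated as a threshold; unspecified demographic/illness variables accepted generously as patient-specific; verbal-memory total score only"
NCT01315002,Scz (DSM),FALSE,TRUE,composite_only,FALSE,2,"smoking status and cholinergic-system polymorphisms are patient-specific variables; single antisaccade error-rate outcome treated as composite"
NCT01207219,Scz/SczAff (DSM),FALSE,FALSE,none,FALSE,0,"no specific features or patient-specific variables; outcome change results unreported, conservatively scored as no usable outcome granularity"
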