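"column","type","description"
"participant_id","character","opaque participant identifier"
"age","integer years","age at interview (> 0)"
"sex","category","male | female"
"ethnicity","category","white_british | south_asian | black | other"
"education","category","none | school_incomplete | school_complete | university_or_apprenticeship | other"
"occupation","category","unemployed | employed | retired | student | housewife | off_sick | other"
"marital_status","category","single | married | divorced_separated | widowed"
"smoking","category","never | past | current"
"alcohol","binary 0/1","any current alcohol use"
"le_illness_self","binary 0/1","threatening life event in the previous 12 months: illness_self"
"le_illness_relative","binary 0/1","threatening life event in the previous 12 months: illness_relative"
"le_death_parent_child_spouse","binary 0/1","threatening life event in the previous 12 months: death_parent_child_spouse"
"le_death_friend_relative","binary 0/1","threatening life event in the previous 12 months: death_friend_relative"
"le_marital_separation","binary 0/1","threatening life event in the previous 12 months: marital_separation"
"le_relationship_breakup","binary 0/1","threatening life event in the previous 12 months: relationship_breakup"
"le_problems_close_person","binary 0/1","threatening life event in the previous 12 months: problems_close_person"
"le_unemployed_seeking","binary 0/1","threatening life event in the previous 12 months: unemployed_seeking"
"le_lost_job","binary 0/1","threatening life event in the previous 12 months: lost_job"
"le_financial_crisis","binary 0/1","threatening life event in the previous 12 months: financial_crisis"
"le_police_court","binary 0/1","threatening life event in the previous 12 months: police_court"
"le_loss_theft_valued","binary 0/1","threatening life event in the previous 12 months: loss_theft_valued"
"disc_unfair_treatment_work","binary 0/1","discrimination experience in the previous 12 months: unfair_treatment_work"
"disc_job_refusal","binary 0/1","discrimination experience in the previous 12 months: job_refusal"
"disc_physical_attack","binary 0/1","discrimination experience in the previous 12 months: physical_attack"
"disc_property_damage","binary 0/1","discrimination experience in the previous 12 months: property_damage"
"disc_racial_insults","binary 0/1","discrimination experience in the previous 12 months: racial_insults"
"cm_hypertension","binary 0/1","comorbidity from clinical records: hypertension"
"cm_diabetes_t1","binary 0/1","comorbidity from clinical records: diabetes_t1"
"cm_diabetes_t2","binary 0/1","comorbidity from clinical records: diabetes_t2"
"cm_obesity","binary 0/1","comorbidity from clinical records: obesity"
"cm_cardiovascular","binary 0/1","comorbidity from clinical records: cardiovascular"
"cm_cancer","binary 0/1","comorbidity from clinical records: cancer"
"cm_copd","binary 0/1","comorbidity from clinical records: copd"
"cm_autoimmune","binary 0/1","comorbidity from clinical records: autoimmune"
"cisr_depressed_mood","binary 0/1","CIS-R depression-section symptom endorsement: depressed_mood"
"cisr_loss_of_interest","binary 0/1","CIS-R depression-section symptom endorsement: loss_of_interest"
"cisr_fatigue","binary 0/1","CIS-R depression-section symptom endorsement: fatigue"
"cisr_concentration","binary 0/1","CIS-R depression-section symptom endorsement: concentration"
"cisr_self_esteem_low","binary 0/1","CIS-R depression-section symptom endorsement: self_esteem_low"
"cisr_guilt","binary 0/1","CIS-R depression-section symptom endorsement: guilt"
"cisr_pessimism_or_suicidality","binary 0/1","CIS-R depression-section symptom endorsement: pessimism_or_suicidality"
"cisr_sleep_disturbance","binary 0/1","CIS-R depression-section symptom endorsement: sleep_disturbance"
"cisr_agitation_or_retardation","binary 0/1","CIS-R depression-section symptom endorsement: agitation_or_retardation"
"cisr_duration_weeks","number >= 0","duration of the current depressive episode, weeks"
"som_diurnal_variation","binary 0/1","ICD-10 somatic-syndrome criterion: diurnal_variation"
"som_early_waking","binary 0/1","ICD-10 somatic-syndrome criterion: early_waking"
"som_loss_of_reactivity","binary 0/1","ICD-10 somatic-syndrome criterion: loss_of_reactivity"
"som_libido_loss","binary 0/1","ICD-10 somatic-syndrome criterion: libido_loss"
"som_psychomotor_change","binary 0/1","ICD-10 somatic-syndrome criterion: psychomotor_change"
"phq2_1","integer 0-3","PHQ-2 item 1"
"phq2_2","integer 0-3","PHQ-2 item 2"
"hamd_1","integer 0-4","HAMD-17 item 1"
"hamd_2","integer 0-4","HAMD-17 item 2"
"hamd_3","integer 0-4","HAMD-17 item 3"
"hamd_4","integer 0-2","HAMD-17 item 4"
"hamd_5","integer 0-2","HAMD-17 item 5"
"hamd_6","integer 0-2","HAMD-17 item 6"
"hamd_7","integer 0-4","HAMD-17 item 7"
"hamd_8","integer 0-4","HAMD-17 item 8"
"hamd_9","integer 0-4","HAMD-17 item 9"
"hamd_10","integer 0-4","HAMD-17 item 10"
"hamd_11","integer 0-4","HAMD-17 item 11"
"hamd_12","integer 0-2","HAMD-17 item 12"
"hamd_13","integer 0-2","HAMD-17 item 13"
"hamd_14","integer 0-2","HAMD-17 item 14"
"hamd_15","integer 0-4","HAMD-17 item 15"
"hamd_16","integer 0-2","HAMD-17 item 16"
"hamd_17","integer 0-2","HAMD-17 item 17"
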