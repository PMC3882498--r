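column,type,levels,description
sample_id,string,,unique participant identifier
status,categorical,case|control,disease status (control = BPH or no clinically definable prostate cancer); required
psa,numeric,,serum prostate specific antigen in ug/L; nonnegative
age,numeric,,age in years at presentation
gleason,integer,2-10,histopathological Gleason score; cases only
grade,categorical,well|moderate|poor,tumor differentiation grade; cases only
population_group,categorical,free text,self-reported ethnolinguistic group (e.g. Pedi Tsonga Venda Tswana other)
clinic,categorical,free text,recruiting clinic
occupation,categorical,free text,occupation class
family_history_pca,categorical,no|yes,family history of prostate cancer
family_history_cancer,categorical,no|yes,family history of any cancer
diabetes,categorical,no|yes,diagnosed diabetes
balding,categorical,none|frontal|vertex|frontal_vertex,male pattern balding
sexual_activity,categorical,no|yes,currently sexually active
ed,categorical,no|yes,erectile dysfunction
aspirin,categorical,no|yes,frequent aspirin use
acne,categorical,no|yes,history of acne
male_breasts,categorical,no|yes,male breast development
std_history,categorical,no|yes,history of sexually transmitted disease
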