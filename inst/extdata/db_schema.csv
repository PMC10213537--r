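column,type,required,description
study_id,character,TRUE,source study identifier
crop,character,TRUE,"wheat, maize or rice"
outcome,character,TRUE,yield or NUE
mean_npk,numeric,TRUE,control mean (t/ha or %)
sd_npk,numeric,FALSE,control SD (may be missing)
n_npk,integer,TRUE,control replicates (>= 3)
mean_npkm,numeric,TRUE,treatment mean
sd_npkm,numeric,FALSE,treatment SD (may be missing)
n_npkm,integer,TRUE,treatment replicates (>= 3)
n_rate_total,numeric,TRUE,total N input (kg N/ha)
substitution_rate,numeric,TRUE,manure N share of total N (%)
climate_type,character,FALSE,"NTM, NTC or STM"
aar_mm,numeric,FALSE,average annual rainfall (mm)
mat_c,numeric,FALSE,mean annual temperature (C)
asd_h,numeric,FALSE,annual sunshine duration (h)
ffp_days,numeric,FALSE,frost-free period (days)
som_gkg,numeric,FALSE,soil organic matter (g/kg)
tn_gkg,numeric,FALSE,soil total N (g/kg)
an_mgkg,numeric,FALSE,alkali-hydrolysable N (mg/kg)
ap_mgkg,numeric,FALSE,available P (mg/kg)
ak_mgkg,numeric,FALSE,available K (mg/kg)
ph,numeric,FALSE,soil pH
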