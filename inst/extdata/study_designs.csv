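# Study designs of the eight clinical profiles driving the scenarios
# (five healthy, two chronic liver disease, one severe renal failure).
# weight_reported = no means the source did not report weights; the 70 kg
# reference default is applied downstream with a provenance flag.
# The chronic-liver-disease profiles are modeled as Child-Pugh class A,
# the class assigned in the source assessment.
study_id,population,route,n_subjects,dose,dose_unit,n_female,age_min,age_max,weight_min,weight_max,weight_reported
1,healthy,oral,6,200,mg,2,20,24,NA,NA,no
2,healthy,oral,5,200,mg,0,21,26,NA,NA,no
3,healthy,iv,6,0.5,mg/kg,2,20,24,NA,NA,no
4,healthy,iv,5,0.5,mg/kg,0,21,26,NA,NA,no
5,healthy,iv,6,0.5,mg/kg,0,21,26,NA,NA,no
6,CP-A,iv,10,0.5,mg/kg,2,22,24,50,65,yes
7,CP-A,oral,10,200,mg,2,22,42,50,65,yes
8,CKD-severe,iv,4,1,mg/kg,1,37,70,75,87,yes
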