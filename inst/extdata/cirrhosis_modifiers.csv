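# Default Child-Pugh physiological modifier table for the cirrhosis model.
# The severity direction and magnitudes follow published cirrhosis PBPK
# physiology compilations (Edginton & Willmann, Clin Pharmacokinet 2008-style
# Child-Pugh parameterizations); they are deliberately editable defaults with
# monotone severity, since exact values are literature-derived rather than
# printed in any single source used here. Factors are dimensionless multipliers
# on the healthy baseline; hematocrit and gfr are absolute replacement values.
label,field,value,unit,provenance
CP-A,liver_volume_factor,0.90,dimensionless,Edginton-Willmann-style CP table
CP-A,hematocrit,0.41,fraction,Edginton-Willmann-style CP table
CP-A,protein_binding_factor,0.95,dimensionless,Edginton-Willmann-style CP table
CP-A,gfr,100,mL/min,Edginton-Willmann-style CP table
CP-A,hepatic_intrinsic_clearance_factor,0.60,dimensionless,Edginton-Willmann-style CP table
CP-A,liver_flow_factor,1.0,dimensionless,left at unity unless user-edited
CP-B,liver_volume_factor,0.80,dimensionless,Edginton-Willmann-style CP table
CP-B,hematocrit,0.38,fraction,Edginton-Willmann-style CP table
CP-B,protein_binding_factor,0.90,dimensionless,Edginton-Willmann-style CP table
CP-B,gfr,70,mL/min,Edginton-Willmann-style CP table
CP-B,hepatic_intrinsic_clearance_factor,0.40,dimensionless,Edginton-Willmann-style CP table
CP-B,liver_flow_factor,1.0,dimensionless,left at unity unless user-edited
CP-C,liver_volume_factor,0.70,dimensionless,Edginton-Willmann-style CP table
CP-C,hematocrit,0.35,fraction,Edginton-Willmann-style CP table
CP-C,protein_binding_factor,0.85,dimensionless,Edginton-Willmann-style CP table
CP-C,gfr,40,mL/min,Edginton-Willmann-style CP table
CP-C,hepatic_intrinsic_clearance_factor,0.25,dimensionless,Edginton-Willmann-style CP table
CP-C,liver_flow_factor,1.0,dimensionless,left at unity unless user-edited
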