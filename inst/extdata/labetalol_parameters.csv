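# Labetalol input parameters. 'engine' marks whether the value drives the
# kinetic model; metadata rows are simulator-internal optimized quantities
# retained verbatim for provenance but not interpreted.
parameter,value,unit,engine
molecular_weight,328.412,g/mol,no
pka,9.38,dimensionless,yes
logp,2.79,log units,yes
fraction_unbound,0.45,fraction,yes
intestinal_permeability,4.67e-5,cm/min,yes
specific_organ_permeability,0.1,L/min,no
total_body_clearance,15,mL/min/kg,yes
specific_clearance,6,L/h,no
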