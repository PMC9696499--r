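# Reference adult (70 kg) organ volumes and regional blood flows.
# ICRP-style reference values assembled from standard physiology compilations
# (ICRP Publication 89 reference adult; regional flow fractions of resting
# cardiac output 6.5 L/min = 390 L/h). All organs scale linearly with body
# weight relative to 70 kg. The gut flow is the portal inflow to the liver;
# the liver flow is the hepatic arterial flow; total hepatic blood flow is
# their sum. The lung carries the whole cardiac output in series.
# Blood pools (arterial_blood, venous_blood) are conduits with zero nominal
# regional flow. Non-lung regional flows sum exactly to the cardiac output.
organ,volume_L_per_70kg,flow_L_per_h_per_70kg
arterial_blood,1.4,0
venous_blood,3.9,0
lung,0.5,390
liver,1.8,25.35
kidney,0.31,74.1
gut,1.1,62.4
muscle,29.0,66.3
adipose,13.0,19.5
skin,3.3,19.5
brain,1.45,46.8
heart,0.33,15.6
bone,10.0,19.5
rest,3.0,40.95
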