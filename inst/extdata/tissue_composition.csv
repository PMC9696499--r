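# Fractional tissue composition (water, neutral lipid, phospholipid) used by
# the tissue-composition partition model. Values follow the published
# compositional tables of Poulin & Theil (J Pharm Sci 2002) for human tissues;
# the 'rest' row is a generic lean-tissue composite. The 'plasma' row is the
# reference phase for all tissue:plasma coefficients.
organ,f_water,f_neutral_lipid,f_phospholipid
adipose,0.18,0.79,0.002
bone,0.45,0.074,0.0011
brain,0.77,0.051,0.0565
gut,0.76,0.049,0.0163
heart,0.78,0.014,0.0111
kidney,0.79,0.021,0.0162
liver,0.75,0.035,0.0250
lung,0.81,0.003,0.0090
muscle,0.76,0.024,0.0072
skin,0.72,0.028,0.0111
rest,0.75,0.040,0.0200
plasma,0.96,0.0023,0.0013
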