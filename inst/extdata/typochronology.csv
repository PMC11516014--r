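# Typochronology config: absolute spans (years BCE, closed intervals) per
# typology code. Battle-axe phases follow the MNB sequence with the late K-L
# types reaching into the earliest LN (2350-2250 BCE overlap with daggers);
# dagger types I-VI are anchored at LNI (2350-1950 BCE) and LNII
# (1950-1700 BCE). Subtype boundaries are editable assumptions.
category,type_code,span_start,span_end
battle_axe,A-B,2850,2700
battle_axe,C-D,2750,2600
battle_axe,E-F,2600,2450
battle_axe,G-J,2500,2350
battle_axe,K-L,2350,2250
flint_dagger,I,2350,2050
flint_dagger,II,2200,1950
flint_dagger,III,1950,1850
flint_dagger,IV,1950,1800
flint_dagger,V,1900,1700
flint_dagger,VI,1800,1700
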