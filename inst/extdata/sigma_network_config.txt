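# three-competitor mass-action benchmark (molecules/cell, per minute)
k_f=24,8,11
k_r=3,6,30
k_cat=5,5,5
C=700,370,110
T=700
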