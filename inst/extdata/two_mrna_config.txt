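# two-mRNA ribosome traffic benchmark (uM, per minute)
n_codons=240,240
k_init=0.2,5
k_elong=50,20
k_term=50,20
abundance=0.2,2
T=79
L=12
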