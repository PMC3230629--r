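#T=700
label	C	tc
sigma70	700	545
sigma54	110	55
sigma28	370	100
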