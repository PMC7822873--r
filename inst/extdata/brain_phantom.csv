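name,amplitude
NAA,12.0
tCr,8.0
Cho,2.5
mI,6.0
Glu,9.0
Gln,3.0
GABA,1.5
Lac,0.6
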