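# Refined recombination frequencies (percent) used for locus placement.
marker	rf	n
h	17.78	450
st	1.23	982
cu	8.29	1204
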