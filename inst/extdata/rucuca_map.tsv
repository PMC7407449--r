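# Standard D. melanogaster chromosome-3 map for the eight visible
# recessives of the multiply marked rucuca chromosome. Positions and bands
# are conventional reference values and can be overridden by the user.
name	chrom	cm	band
ru	3	0.0	61F1
h	3	26.5	66D10
th	3	43.2	72D1
st	3	44.0	73A3
cu	3	50.0	86D2
sr	3	62.0	90E1
e	3	70.7	93C7
ca	3	100.7	99B9
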