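# Parental/recombinant tallies of the 113 scored males against each
# visible marker. Note on ca: the published parental class subtotals
# (42 + 32 = 74) contradict both the 113-male total and the published
# RF of 43.3 (= 100*49/113); the value consistent with both (64) is
# recorded here.
marker	parental	recombinant	replicate
ru	62	51	1
h	79	34	1
th	110	3	1
st	108	5	1
cu	105	8	1
sr	94	19	1
e	86	27	1
ca	64	49	1
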