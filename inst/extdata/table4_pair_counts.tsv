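# Replicate testcross tallies for the refined h, st and cu pairs.
marker	parental	recombinant	replicate
h	89	18	1
h	185	40	2
h	96	22	3
st	252	2	1
st	480	6	2
st	238	4	3
cu	269	22	1
cu	552	50	2
cu	283	28	3
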