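# Scored F3 males from the recombination-mapping cross:
# marker haplotype (mut/wt per visible marker) and inferred
# lethal-locus state from the individual testcross.
ru	h	th	st	cu	sr	e	ca	locus_state
mut	mut	mut	wt	wt	wt	wt	wt	l+
mut	mut	mut	mut	wt	wt	wt	wt	l+
mut	mut	mut	mut	mut	wt	wt	wt	l+
mut	mut	mut	mut	mut	mut	wt	wt	l+
mut	mut	mut	mut	mut	mut	mut	wt	l+
mut	mut	mut	mut	mut	mut	mut	wt	l+
mut	mut	mut	mut	mut	mut	mut	wt	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
mut	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	mut	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	mut	mut	mut	mut	mut	mut	l+
wt	wt	wt	mut	mut	mut	mut	mut	l
wt	wt	wt	wt	mut	mut	mut	mut	l
wt	wt	wt	wt	mut	mut	mut	mut	l+
wt	wt	wt	wt	wt	mut	mut	mut	l
wt	wt	wt	wt	wt	mut	mut	mut	l
wt	wt	wt	wt	wt	wt	mut	mut	l
wt	wt	wt	wt	wt	wt	mut	mut	l
wt	wt	wt	wt	wt	wt	mut	mut	l
wt	wt	wt	wt	wt	wt	mut	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	mut	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
wt	wt	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	mut	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	wt	l
mut	wt	wt	wt	wt	wt	wt	mut	l
mut	wt	wt	wt	wt	wt	wt	mut	l
mut	wt	wt	wt	wt	wt	wt	mut	l
mut	wt	wt	wt	wt	wt	mut	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	wt	wt	mut	l
mut	mut	wt	wt	wt	mut	mut	mut	l
mut	mut	wt	wt	wt	mut	mut	mut	l
mut	mut	wt	wt	wt	mut	mut	mut	l
mut	mut	wt	wt	wt	mut	mut	mut	l
mut	mut	wt	wt	wt	mut	mut	mut	l
mut	wt	wt	wt	wt	mut	mut	mut	l
mut	wt	wt	wt	wt	mut	mut	mut	l
mut	wt	wt	wt	wt	mut	mut	mut	l
mut	mut	wt	wt	mut	mut	mut	mut	l
mut	mut	mut	mut	mut	wt	mut	mut	l+
wt	wt	mut	mut	mut	mut	wt	mut	l+
wt	wt	mut	mut	mut	mut	mut	wt	l+
wt	wt	mut	mut	mut	mut	mut	wt	l+
wt	wt	mut	mut	mut	mut	mut	wt	l+
wt	wt	mut	mut	wt	wt	wt	wt	l+
wt	wt	wt	wt	wt	mut	mut	wt	l+
wt	mut	wt	wt	wt	wt	wt	wt	l+
wt	mut	mut	mut	mut	mut	mut	wt	l
wt	mut	mut	mut	mut	mut	mut	wt	l+
wt	mut	mut	mut	mut	mut	mut	wt	l+
wt	mut	mut	mut	mut	mut	mut	wt	l+
wt	mut	mut	mut	mut	mut	mut	wt	l+
wt	mut	mut	mut	mut	mut	wt	wt	l+
wt	mut	mut	mut	mut	wt	wt	wt	l+
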