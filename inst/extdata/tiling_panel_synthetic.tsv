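# SYNTHETIC tiling-PCR panel over the candidate locus: abutting 945 bp
# amplicons; the one spanning 3L:15826279..15827223 fails to amplify in
# the mutant, all others amplify at wild-type size.
id	contig	start	end	outcome	observed_size
amp01	3L	15824389	15825333	amplified	945
amp02	3L	15825334	15826278	amplified	945
amp03	3L	15826279	15827223	failed	NA
amp04	3L	15827224	15828168	amplified	945
amp05	3L	15828169	15829113	amplified	945
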