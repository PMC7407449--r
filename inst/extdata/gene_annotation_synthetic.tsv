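# SYNTHETIC gene-to-band annotation for the tested genes.
gene	arm	band
DCP2	3L	72A1
CG7139	3L	71F3
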