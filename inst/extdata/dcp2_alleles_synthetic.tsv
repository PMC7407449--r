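# SYNTHETIC allele complementation tests for genes near the candidate
# region (outcomes mirror the mapping narrative; ids are stand-ins).
gene	allele	outcome
DCP2	insA	fails
DCP2	insB	fails
CG7139	insC	complements
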