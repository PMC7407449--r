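# SYNTHETIC deficiency panel: breakpoints are stand-ins constructed around
# a locus in 71F4-71F5 (published deficiency breakpoints live in stock-center
# records and are not reproduced here).
id	arm	del_start	del_end	outcome
DfS01	3L	71E1	72B2	fails
DfS02	3L	71F1	72A1	fails
DfS03	3L	71F2	72C1	fails
DfS04	3L	71F4	72A2	fails
DfS05	3L	71A1	71F3	complements
DfS06	3L	71F6	72D1	complements
DfS07	3L	70A1	71E2	complements
DfS08	3L	72B1	73C1	complements
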