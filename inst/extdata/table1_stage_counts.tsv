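# Intercross of lethal/balancer flies: per-class counts through the
# developmental stages (non-Tubby = homozygous mutant, Tubby = balancer
# heterozygote).
class	stage	count
NonTubby	larvae	468
NonTubby	pupae	313
NonTubby	eclosed	0
Tubby	larvae	473
Tubby	pupae	468
Tubby	eclosed	465
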