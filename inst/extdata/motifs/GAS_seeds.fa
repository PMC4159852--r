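>GAS_occ01
TTCCCGGAA
>GAS_occ02
TTCCCGGAA
>GAS_occ03
TTCCCGGAA
>GAS_occ04
TTCCCGGAA
>GAS_occ05
TTCCCGGAA
>GAS_occ06
TTCCCGGAA
>GAS_occ07
TTCCCGGAA
>GAS_occ08
TTCCTGGAA
>GAS_occ09
TTCCGGGAA
>GAS_occ10
TTCCAGGAA
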