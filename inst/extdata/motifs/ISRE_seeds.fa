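>ISRE_occ01
AGTTTCACTTTC
>ISRE_occ02
AGTTTCACTTTC
>ISRE_occ03
AGTTTCACTTTC
>ISRE_occ04
AGTTTCACTTTC
>ISRE_occ05
AGTTTCACTTTC
>ISRE_occ06
AGTTTCACTTTC
>ISRE_occ07
AGTTTCACTTTC
>ISRE_occ08
AGTTTCGCTTTC
>ISRE_occ09
AGTTTCTCTTTC
>ISRE_occ10
AGTTTCCCTTTC
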