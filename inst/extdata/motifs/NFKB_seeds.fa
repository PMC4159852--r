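>NFKB_occ01
GGGACTTTCC
>NFKB_occ02
GGGACTTTCC
>NFKB_occ03
GGGACTTTCC
>NFKB_occ04
GGGACTTTCC
>NFKB_occ05
GGGACTTTCC
>NFKB_occ06
GGGACTTTCC
>NFKB_occ07
GGGACTTTCC
>NFKB_occ08
GGGGCTTTCC
>NFKB_occ09
GGGACTCTCC
>NFKB_occ10
GGGACTTCCC
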