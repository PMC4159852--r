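>IRF_occ01
AAAGTGAAAG
>IRF_occ02
AAAGTGAAAG
>IRF_occ03
AAAGTGAAAG
>IRF_occ04
AAAGTGAAAG
>IRF_occ05
AAAGTGAAAG
>IRF_occ06
AAAGTGAAAG
>IRF_occ07
AAAGTGAAAG
>IRF_occ08
AAAGTGAAAC
>IRF_occ09
AAAGCGAAAG
>IRF_occ10
AAAGTGAAAT
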