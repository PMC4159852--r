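gene	localization
APOC1	secreted
APOE	secreted
CCL18	secreted
CCL19	secreted
CCL2	secreted
CCL4	secreted
CCL5	secreted
CP	secreted
CXCL10	secreted
CXCL2	secreted
CXCL9	secreted
GZMA	secreted
GZMK	secreted
HAPLN1	secreted
HPSE	secreted
IBSP	secreted
IGJ	secreted
LAMB1	secreted
MMP9	secreted
PTX3	secreted
SCG2	secreted
SERPINE1	secreted
SPINK1	secreted
SPP1	secreted
THBS1	secreted
THBS2	secreted
TNFRSF11B	secreted
TNS3	secreted
VCAN	secreted
VEGFC	secreted
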