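gene	known_stat1_regulation	ISRE	STAT1_NFKB	STAT1_IRF
APOC1	no	+	-	-
APOE	no	+	-	-
CCL18	no	+	+	+
CCL19	no	+	+	+
CCL2	yes	+	+	+
CCL4	yes	+	+	+
CCL5	yes	+	+	+
CP	no	+	-	+
CXCL10	yes	+	+	-
CXCL2	no	-	+	-
CXCL9	yes	+	-	-
GZMA	no	+	-	+
GZMK	no	+	-	+
HAPLN1	no	+	+	+
HPSE	no	-	-	-
IBSP	no	+	-	-
IGJ	no	-	+	+
LAMB1	no	+	+	+
MMP9	yes	-	+	+
PTX3	no	+	-	+
SCG2	no	+	-	+
SERPINE1	yes	+	+	+
SPINK1	no	+	-	+
SPP1	no	+	+	+
THBS1	no	+	-	+
THBS2	no	+	-	-
TNFRSF11B	no	+	+	+
TNS3	no	+	-	-
VCAN	no	+	+	+
VEGFC	yes	+	-	+
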