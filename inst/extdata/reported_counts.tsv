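quantity	value
snps_autosome_x_total	10862507
snps_in_catalog_a	7658805
snps_in_catalog_b	9134659
snps_in_neither	1390686
indels_total	2815215
indels_coding	3606
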