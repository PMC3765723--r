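cell_line	comparison	class	total_sites	sites_in_interaction
K562	cctcf_vs_nonconst	cCTCF	23577	14178
K562	cctcf_vs_nonconst	all_ctcf_excluding_cctcf	81464	13316
K562	cohesin_vs_noncohesin	cCTCF_cCohesin	12014	8714
K562	cohesin_vs_noncohesin	cCTCF_excluding_cCohesin	11563	5464
MCF7	cctcf_vs_nonconst	cCTCF	23641	19398
MCF7	cctcf_vs_nonconst	all_ctcf_excluding_cctcf	67752	23701
MCF7	cohesin_vs_noncohesin	cCTCF_cCohesin	12001	10796
MCF7	cohesin_vs_noncohesin	cCTCF_excluding_cCohesin	11640	8602
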