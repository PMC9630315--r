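name	alphabet	sequence	length_nt	genomic_span_hg19	description
TFO2-23	RNA	GCGGCGGAGGAAAGAGAAAGGAG	23	NA	Core triplex-forming region (TFR2) of the lncRNA; third strand in the melting, CD and NMR assays
EPHA2_purine	DNA	AGAGGGTAAGGAGATAGGAGAAACC	25	chr1:16,478,543-16,478,567	EPHA2 intron-1 target, purine(GA)-rich strand
EPHA2_pyrimidine	DNA	GGTTTCTCCTATCTCCTTACCCTCT	25	chr1:16,478,543-16,478,567	EPHA2 intron-1 target, pyrimidine(CT)-rich strand
EPHA2_hairpin	DNA	GGTTTCTCCTATCTCCTTACCCTCTTTTTTAGAGGGTAAGGAGATAGGAGAAACC	55	chr1:16,478,543-16,478,567	EPHA2 target strands joined by a 5-T linker (intramolecular duplex)
ADM_purine	DNA	GTGGCTGAGGAAAGA	15	chr11:10,326,521-10,326,535	ADM target, purine(GA)-rich strand
ADM_pyrimidine	DNA	TCTTTCCTCAGCCAC	15	chr11:10,326,521-10,326,535	ADM target, pyrimidine(CT)-rich strand
ADM_hairpin	DNA	TCTTTCCTCAGCCACTTTTTGTGGCTGAGGAAAGA	35	chr11:10,326,521-10,326,535	ADM target strands joined by a 5-T linker (intramolecular duplex)
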