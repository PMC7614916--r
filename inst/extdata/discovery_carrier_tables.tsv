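unit	class	cohort	case_carriers	case_total	control_carriers	control_total
IL18RAP_3UTR	UTR3	discovery	6	3955	12	1819
NEK1_ORF	ORF	discovery	127	3955	19	1819
SOD1_ORF	ORF	discovery	36	3955	0	1819
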