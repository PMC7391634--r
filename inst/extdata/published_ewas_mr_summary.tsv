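# Published per-CpG summary of the hypospadias case-control and case-only EWAS
# (45 cases / 46 controls; 21 chordee vs 24; 9 severe vs 36 moderate) and the
# 2SLS Mendelian randomization using meQTL instruments. Positions are build 37.
# delta_beta_printed is the printed comparison-minus-case difference; group
# means are printed to three decimals.
design	probe_id	chrom	pos	gene	case_mean	comparison_mean	delta_beta_printed	ewas_p	ewas_q	n_meqtls	mr_2sls_p
hypospadias_case_control	cg04714159	1	47301259	CYP4B1-CYP4Z2P	0.875	0.913	0.038	9.3e-07	0.109	13	3.9e-06
hypospadias_case_control	cg14436889	1	108231706	VAV3	0.591	0.748	0.157	5.4e-07	0.109	4	9.8e-15
hypospadias_case_control	cg26143053	2	3718125	ALLC	0.905	0.927	0.023	7.5e-07	0.109	12	0.003
hypospadias_case_control	cg03368481	2	76014479	EVA1A-MRPL19-GCFC2	0.773	0.847	0.074	8.8e-07	0.109	12	0.191
hypospadias_case_control	cg25918138	3	38408147	XYLB	0.926	0.944	0.018	1.3e-06	0.132	12	0.001
hypospadias_case_control	cg14906547	9	33908335	UBE2R2	0.920	0.944	0.025	7.4e-07	0.109	13	8.8e-06
hypospadias_case_control	cg25196688	12	3421025	TSPAN9-PRMT8-EFCAB4B	0.392	0.506	0.114	1.7e-07	0.109	13	5.5e-10
hypospadias_case_control	cg00752630	12	125591239	AACS	0.884	0.920	0.037	2.1e-06	0.175	11	0.159
hypospadias_case_control	cg08539758	17	57638482	YPEL2-DHX40-PTRH2	0.732	0.701	-0.031	6.0e-07	0.109	5	1.7e-05
hypospadias_case_control	cg26638975	19	51876721	NKG7	0.780	0.754	-0.026	2.1e-06	0.175	8	0.025
chordee_case_only	cg07999371	1	26847004	DHDDS-HMGN2-RPS6KA1	0.558	0.576	0.018	8.5e-07	0.148	20	0.093
chordee_case_only	cg05045951	2	70485377	PCYOX1	0.024	0.021	-0.003	1.6e-06	0.148	10	5.2e-04
chordee_case_only	cg15945209	2	133039143	ANKRD30BL-GPR39	0.575	0.544	-0.031	5.5e-07	0.148	21	1.3e-07
chordee_case_only	cg24241688	3	13036636	IQSEC1	0.097	0.085	-0.012	3.3e-07	0.135	15	0.004
chordee_case_only	cg06484075	4	184393241	CDKN2AIP-ING2	0.552	0.592	0.040	1.4e-06	0.148	12	0.011
chordee_case_only	cg19445285	12	32480897	BICD1	0.907	0.886	-0.020	1.6e-06	0.148	4	1.2e-08
chordee_case_only	cg07509211	14	54950145	GMFB	0.745	0.708	-0.038	1.4e-07	0.114	2	1.3e-05
chordee_case_only	cg16752029	16	27214750	KDM8	0.039	0.043	0.004	1.2e-06	0.148	4	0.041
chordee_case_only	cg15014976	19	52101661	SIGLEC6-ZNF175	0.875	0.862	-0.013	1.4e-06	0.148	3	0.002
severity_case_only	cg15231374	1	160132381	ATP1A4	0.663	0.684	0.022	7.0e-07	0.119	13	0.079
severity_case_only	cg22788109	1	225867346	ENAH-SRP9	0.814	0.747	-0.067	8.9e-08	0.041	23	6.3e-10
severity_case_only	cg21454600	3	18772063	SATB1-KCNH8	0.875	0.894	0.020	9.4e-07	0.128	7	3.8e-04
severity_case_only	cg15242360	6	39854530	DAAM2	0.841	0.872	0.031	7.3e-07	0.119	5	1.0e-04
severity_case_only	cg01749436	8	9756178	TNKS-MSRA	0.056	0.039	-0.017	4.2e-07	0.114	14	0.001
severity_case_only	cg10817615	11	45687277	CHST1	0.523	0.461	-0.062	1.0e-07	0.041	5	1.9e-09
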