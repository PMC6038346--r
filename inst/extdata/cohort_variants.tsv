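case_id	gene	allele	variant_class	zygosity	criteria	in_db	de_novo	override_class	confirmed	homology_flagged	printed_class	source
OTO.008	MYO15A	c.8050T>C p.(Tyr2684His)	SNV	heterozygous	PM2,PM3,PP1,PP3	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.008	MYO15A	c.8968-1G>T	SNV	heterozygous	PVS1,PM2,PP1	FALSE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.001	STRC	whole-gene deletion	cnv_del	homozygous	PVS1,PM2,PM3	TRUE	FALSE		TRUE	TRUE	pathogenic	case_table
OTO.033	STRC	whole-gene deletion	cnv_del	homozygous	PVS1,PM2,PM3	TRUE	FALSE		TRUE	TRUE	pathogenic	case_table
OTO.033	TECTA	c.3107G>A p.(Cys1036Tyr)	SNV	heterozygous	PP1,PP3	TRUE	FALSE		TRUE	FALSE	VUS	narrative
OTO.050	RDX	exon 2 deletion	cnv_del	homozygous	PVS1,PM2	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.009	BSND	c.23G>A p.(Arg8Gln)	SNV	homozygous	PM1,PM2,PM5,PP3	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.006	SLC26A4	c.412G>T p.(Val138Phe)	SNV	heterozygous	PS3,PS(PM3),PP3	TRUE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.006	SLC26A4	c.1370A>T p.(Asn457Ile)	SNV	heterozygous	PM1,PM2,PM3,PP3	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.018	CDH23	c.4488G>C p.(Gln1496His)	SNV	heterozygous	PS3,PM2,PM3,PP1,PP3	TRUE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.018	CDH23	duplication of exons 11-15	cnv_dup	heterozygous	PM2,PM3,PM4	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.004	USH2A	c.11864G>A p.(Trp3955*)	SNV	homozygous	PVS1,PS(PM3)	TRUE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.005	USH2A	c.1724G>A p.(Cys575Tyr)	SNV	homozygous	PS(PM3),PM2,PP3	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.014	USH2A	c.1724G>A p.(Cys575Tyr)	SNV	heterozygous	PS(PM3),PM2,PP3	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.014	USH2A	c.1841-2A>G	SNV	heterozygous	PVS1,PS(PM3),PS3,PM2	TRUE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.003	P2RX2	c.178G>T p.(Val60Leu)	SNV	heterozygous	PS3,PM2,PP1	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.043	ACTG1	c.434C>G p.(Ser145Cys)	SNV	heterozygous	PM1,PM2,PP2,PP3	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.023	ACTG1	c.548G>A p.(Arg183Gln)	SNV	heterozygous	PS2,PP(PM2),PP2,PP3	FALSE	TRUE		TRUE	FALSE	likely_pathogenic	case_table
OTO.041	ACTG1	c.848T>C p.(Met283Thr)	SNV	heterozygous	PS2,PM2,PP2	FALSE	TRUE		TRUE	FALSE	likely_pathogenic	case_table
OTO.011	MITF	c.909G>A p.(Thr303Thr)	SNV	heterozygous	PS3,PM2,PP1	TRUE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.051	SOX10	c.135_154del p.(Ser45Argfs*15)	indel	heterozygous	PVS1,PM2,PP3	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.019	GATA3	c.1018A>C p.(Asn340His)	SNV	heterozygous	PM1,PM2,PM6,PP2,PP3	FALSE	TRUE		TRUE	FALSE	likely_pathogenic	case_table
OTO.010	CHD7	c.235A>T p.(Lys79*)	SNV	heterozygous	PVS1,PM2,PP4	FALSE	FALSE		TRUE	FALSE	pathogenic	case_table
OTO.015	POU3F4	c.692C>T p.(Thr231Ile)	SNV	hemizygous	PM1,PM2,PP2,PP3	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.016	PRPS1	c.826C>T p.(Pro276Ser)	SNV	hemizygous	PM1,PM2,PP2,PP3	FALSE	FALSE		TRUE	FALSE	likely_pathogenic	case_table
OTO.007	COL4A5	c.3525_3529dup p.(Pro1177Leufs*124)	indel	hemizygous	PVS1,PM2,PM6	FALSE	TRUE		TRUE	FALSE	pathogenic	case_table
OTO.028	OTOA	whole-gene deletion	cnv_del	heterozygous	PVS1,PM3	FALSE	FALSE	pathogenic	TRUE	TRUE	pathogenic	case_table
OTO.028	OTOA	c.1282G>T p.(Val428Phe)	SNV	hemizygous	PM2,PM3,PP2	FALSE	FALSE		TRUE	TRUE	VUS	case_table
OTO.044	LOXHD1	c.3571A>G p.(Thr1191Ala)	SNV	homozygous	PM2,PP3	FALSE	FALSE		TRUE	FALSE	VUS	case_table
OTO.045	SLC26A4	c.695T>G p.(Leu232Arg)	SNV	homozygous	PM1,PM2,PP3	FALSE	FALSE		TRUE	FALSE	VUS	case_table
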