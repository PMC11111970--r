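id	svtype	chrom1	pos1	chrom2	pos2	size	support_pacbio	support_ont	support_illumina	callsets	genes
inv12_p13q23	INV	chr12	11873746	chr12	96556989	84683243	9	18	16	illumina,ont,pacbio
t12_21_etv6_runx1	BND	chr12	11874372	chr21	34948109	0	6	8	11	illumina,ont,pacbio	ETV6::RUNX1
t16_21_runx1_prdm7	BND	chr16	90067326	chr21	34947932	0	19	18	32	illumina,ont,pacbio	RUNX1::PRDM7,CBFA2T3
t4_16	BND	chr16	90067537	chr4	159785190	0	5	7	8	illumina,ont,pacbio	PRDM7
t4_12	BND	chr12	96556785	chr4	159785199	0	12	17	11	illumina,ont,pacbio
t5_12_lrp6	BND	chr12	12123786	chr5	128865814	0	6	9	16	illumina,ont,pacbio	LRP6::SLC27A6
t5_12_phax	BND	chr12	11540006	chr5	126620210	0	13	16	14	illumina,ont,pacbio	PHAX::AC007450.2
del3_p22p14	DEL	chr3	35660443	chr3	61437807	25777364	10	16	11	illumina,ont,pacbio	ARPP21,FHIT,SETD2
del3_q26	DEL	chr3	177050707	chr3	177196318	145611	12	5	25	illumina,ont,pacbio	TBL1XR1
del5_q31	DEL	chr5	143197445	chr5	143402107	204662	7	8	19	illumina,ont,pacbio	NR3C1::ARHGAP26
del6_q21	DEL	chr6	111426787	chr6	111563892	137105	11	6	19	illumina,ont,pacbio	TRAF3IP2::REV3L
del12_q21	DEL	chr12	91884416	chr12	92144292	259876	12	8	13	illumina,ont,pacbio	BTG1
del14_q24	DEL	chr14	72752203	chr14	72892376	140173	11	16	15	illumina,ont,pacbio	DPF3
inv16_p12	INV	chr16	21583122	chr16	22699431	1116309	13	16	18	illumina,ont,pacbio
del18_q21	DEL	chr18	48950471	chr18	49053159	102688	6	9	13	illumina,ont,pacbio	SMAD7
del18_q23_nfatc1	DEL	chr18	79384761	chr18	79516951	132190	3	7	10	illumina,ont,pacbio	NFATC1
del18_q23	DEL	chr18	75992809	chr18	76208899	216090	9	5	16	illumina,ont,pacbio
del22_q11_vpreb1	DEL	chr22	22031472	chr22	22245538	214066	6	9	29	illumina,ont,pacbio	PRAMENP,VPREB1
del22_q11_igll5	DEL	chr22	22713200	chr22	22904992	191792	5	11	21	illumina,ont,pacbio	IGLL5
ins1_2	BND	chr1	146784567	chr2	89027169	0	9	13	5	ont,pacbio
dup1_p21	DUP	chr1	103561098	chr1	103676921	115823	9	7	3	ont,pacbio
inv2_p11	INV	chr2	88861924	chr2	90221383	1359459	7	9	20	illumina,ont
del9_p21	DEL	chr9	20676192	chr9	23121222	2445030	20	19	20	illumina	CDKN2A,FOCAD,IFN,KLHL9
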