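snp_id	chrom	pos	effect_allele	other_allele	beta	p_value
rs7574670	1	1750000	A	G	0.0199	0.000123
rs13225097	2	2500000	A	C	0.0151	0.000846
rs196808	3	3250000	A	G	0.0147	0.005017
rs6885750	4	4000000	T	C	-0.0096	0.010573
rs4841679	5	4750000	T	C	0.0235	0.011172
rs870870	6	5500000	A	G	-0.0088	0.018874
rs2665316	7	6250000	T	C	-0.0174	0.019226
rs4405319	8	7000000	T	C	0.0299	0.031478
rs11724118	9	7750000	A	C	0.0144	0.04592
rs10804992	10	8500000	T	G	-0.0063	0.046243
rs6552502	11	9250000	A	C	0.0106	0.058479
rs397234	12	10000000	A	C	-0.0075	0.058594
rs11898925	13	10750000	A	G	0.0186	0.061942
rs1866816	14	11500000	T	C	0.0094	0.061986
rs7807790	15	12250000	T	G	-0.0129	0.062096
rs2965106	16	13000000	T	G	0.0277	0.062112
rs275146	17	13750000	A	C	-0.0206	0.062816
rs7155790	18	14500000	T	G	-0.0273	0.065848
rs9840453	19	15250000	T	G	0.0108	0.06717
rs11693862	20	16000000	T	G	0.0148	0.073821
rs1492377	21	16750000	A	C	-0.023	0.074815
rs1377315	22	17500000	T	C	-0.0125	0.083513
rs4686837	1	18250000	T	C	0.0129	0.088538
rs4803789	2	19000000	A	G	0.0198	0.089959
rs10520768	3	19750000	A	G	0.0256	0.090182
rs2295308	4	20500000	T	C	0.015	0.093524
rs7598551	5	21250000	A	C	-0.014	0.094168
rs7332334	6	22000000	T	C	-0.0249	0.101271
rs728586	7	22750000	T	C	-0.0186	0.10354
rs4779876	8	23500000	T	G	-0.0265	0.10393
rs1935492	9	24250000	T	G	0.0213	0.103989
rs7983099	10	25000000	T	G	-0.0247	0.11213
rs923554	11	25750000	A	G	-0.0279	0.11888
rs1885414	12	26500000	A	C	-0.0079	0.123295
rs9863801	13	27250000	T	C	0.0142	0.126196
rs11891202	14	28000000	A	C	0.0102	0.135653
rs4382157	15	28750000	A	C	-0.028	0.136635
rs5753103	16	29500000	T	C	-0.019	0.150747
rs17035960	17	30250000	T	C	0.0163	0.151128
rs884972	18	31000000	A	G	0.0197	0.151753
rs10002944	19	31750000	A	C	0.0171	0.154237
rs10145606	20	32500000	T	G	0.0113	0.156256
rs892114	21	33250000	A	G	-0.0157	0.159405
rs6543408	22	34000000	A	C	0.0139	0.178625
rs4766912	1	34750000	T	G	-0.0059	0.184907
rs7138803	2	35500000	T	G	0.0277	0.185122
rs2544164	3	36250000	T	C	-0.0229	0.197849
rs12219445	4	37000000	A	G	-0.0215	0.198058
rs1664256	5	37750000	A	G	0.021	0.199221
rs11603179	6	38500000	A	G	0.011	0.201429
rs11820303	7	39250000	A	G	-0.0202	0.211331
rs2341647	8	40000000	T	G	-0.0191	0.217823
rs6888754	9	40750000	A	C	-0.0287	0.219617
rs9808140	10	41500000	A	C	0.0051	0.221567
rs1058065	11	42250000	A	C	0.0062	0.22319
rs12731669	12	43000000	A	C	-0.0236	0.231006
rs7243066	13	43750000	A	C	-0.0186	0.238047
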