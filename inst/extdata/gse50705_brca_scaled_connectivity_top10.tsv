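gene	K_mcf7	rank_mcf7	K_brca	rank_brca
SUSD2	0.787126168	68	6.48E-05	9995
CLU	0.878769987	16	0.000544507	9933
BCAR3	0.78900237	67	0.001091298	9861
TMPRSS3	0.767847573	82	0.000989588	9875
OLFM1	0.70620407	181	0.000370951	9960
SLC24A3	0.748824023	108	0.000982308	9877
DEGS1	0.72618254	148	0.00099857	9874
NPY1R	0.752667373	103	0.001839083	9775
PLK2	0.722418194	156	0.001623592	9802
CYP2J2	0.674845098	238	0.000986705	9876
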