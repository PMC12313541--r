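exposure	gwas_id	n_snp	pval	or	or_low	or_high
Drinks per week	NA	91	1.14e-04	1.26	1.12	1.42
Alcohol intake frequency	ukb-b-5779	79	1.10e-05	1.18	1.09	1.26
Water intake	ukb-b-14898	140	0.03	1.16	1.01	1.34
Milk intake	ebi-a-GCST90096916	9	0.23	0.21	0.02	2.65
Honey intake	ukb-b-6066	39	0.79	0.98	0.82	1.17
Coffee intake	ukb-b-5237	39	0.31	0.87	0.67	1.13
Orange juice intake	ukb-b-2763	12	0.44	0.92	0.74	1.14
Pure fruit/vegetable juice intake	ukb-b-337	8	0.14	1.34	0.91	1.97
Grapefruit juice intake	ukb-b-14351	19	0.28	0.80	0.53	1.21
Yogurt intake	ukb-b-7753	9	0.06	0.80	0.63	1.01
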