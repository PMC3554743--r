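mirna_id	log2_fc	direction	p_adj
hsa-novel-mir-27	10.32	Up	7.84E-55
hsa-novelmiR-35	9.95	Up	5.69E-43
hsa-novel-miR-14	9.59	Up	7.59E-34
hsa-novel-mir-8	9.31	Up	4.43E-28
hsa-novel-miR-12	8.84	Up	8.36E-21
hsa-novel-miR-25	7.99	Up	2.48E-12
hsa-novel-mir-15	7.57	Up	1.23E-09
hsa-novel-miR-17	1.39	Up	1.75E-03
hsa-novel-miR-26	1.12	Up	1.58E-08
hsa-novel-miR-43	-10.14	Down	3.29E-48
hsa-novel-miR-65	-9.644	Down	1.24E-34
hsa-novel-miR-51	-8.12	Down	3.59E-13
hsa-novel-miR-41	-8.08	Down	7.06E-13
hsa-novel-miR-64	-7.48	Down	4.18E-09
hsa-novel-miR-50	-7.29	Down	3.06E-08
hsa-novel-miR-72	-7.29	Down	3.05E-08
hsa-novel-miR-71	-7.23	Down	5.87E-08
hsa-novel_miR-58	-7.08	Down	2.25E-07
hsa-novel-miR-57	-6.74	Down	3.13E-06
hsa-novel-miR-13	-2.82	Down	1.41E-21
hsa-novel-miR-19	-1.04	Down	4.77E-05
hsa-novel-miR-5	-1.01	Down	2.18E-06
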