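mirna_id	log2_fc	direction	p_adj
hsa-miR-181a-3p	9.04	Up	1.56E-23
hsa-miR-3660	7.87	Up	1.95E-11
hsa-miR-2682-5p	7.77	Up	7.78E-11
hsa-miR-551b-3p	7.39	Up	9.63E-09
hsa-miR-3117-3p	7.26	Up	3.73E-08
hsa-miR-551b-5p	7.11	Up	1.49E-07
hsa-miR-548h-5p	6.95	Up	5.93E-07
hsa-miR-296-3p	6.60	Up	8.05E-29
hsa-miR-4488	5.95	Up	4.10E-35
hsa-miR-296-5p	5.84	Up	3.88E-78
hsa-miR-4454	5.19	Up	3.07E-85
hsa-miR-4687-3p	4.37	Up	8.32E-26
hsa-miR-3654	3.38	Up	1.21E-25
hsa-miR-577	2.94	Up	8.64E-05
hsa-miR-4508	2.9	Up	5.94E-06
hsa-miR-3687	2.49	Up	2.04E-05
hsa-miR-4448	2.45	Up	1.66E-04
hsa-miR-4426	2.23	Up	3.53E-05
hsa-miR-720	2.08	Up	1.21E-05
hsa-miR-4485	1.71	Up	6.14E-08
hsa-miR-877-5p	1.68	Up	1.92E-82
hsa-miR-3679-5p	1.45	Up	5.53E-04
hsa-miR-21-3p	1.40	Up	7.87E-13
hsa-miR-338-3p	-11.63	Down	4.47E-133
hsa-miR-486-3p	-8.90	Down	2.14E-21
hsa-miR-944	-8.39	Down	1.61E-15
hsa-miR-2277-5p	-8.01	Down	2.67E-12
hsa-miR-338-5p	-8.01	Down	2.68E-12
hsa-miR-139-3p	-7.96	Down	9.21E-75
hsa-miR-4427	-7.36	Down	1.58E-08
hsa-miR-3186-3p	-7.01	Down	4.40E-07
hsa-miR-1269b	-6.74	Down	3.15E-06
hsa-miR-3674	-6.74	Down	3.16E-06
hsa-miR-3910	-6.74	Down	3.17E-06
hsa-miR-642a-3p	-6.74	Down	5.10E-32
hsa-miR-486-5p	-6.46	Down	2.81E-100
hsa-miR-203	-6.30	Down	3.19E-89
hsa-miR-1277-3p	-6.16	Down	3.01E-41
hsa-miR-1277-5p	-5.90	Down	3.84E-18
hsa-miR-1250	-5.71	Down	2.05E-169
hsa-miR-139-5p	-5.46	Down	3.71E-25
hsa-miR-335-5p	-5.26	Down	2.00E-41
hsa-miR-362-3p	-5.01	Down	3.36E-10
hsa-miR-1255a	-4.92	Down	1.25E-62
hsa-miR-3622a-5p	-4.83	Down	4.30E-09
hsa-miR-1293	-4.67	Down	2.87E-08
hsa-miR-2116-3p	-4.64	Down	3.67E-14
hsa-miR-365a-3p	-4.52	Down	8.20E-62
hsa-miR-365b-3p	-4.52	Down	8.29E-62
hsa-miR-4501	-4.22	Down	2.27E-06
hsa-miR-196a-3p	-4.14	Down	4.15E-06
hsa-miR-500a-5p	-4.01	Down	2.94E-09
hsa-miR-500b	-4.01	Down	2.94E-09
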