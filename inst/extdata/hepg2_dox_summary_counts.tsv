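metric	value
known_sig_up	23
known_sig_down	246
exon_unique_sense_parental	25847
exon_unique_antisense_parental	2332
exon_unique_sense_resistant	173619
exon_unique_antisense_resistant	1546
exon_total_sense_parental	32526
exon_total_antisense_parental	2985
exon_total_sense_resistant	260480
exon_total_antisense_resistant	2546
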