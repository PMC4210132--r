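strain	treatment	symbol	value	unit
AJ	control	PTGS1	1.00	ratio
AJ	control	ALOX5	1.00	ratio
AJ	control	PTGDS	1.00	ratio
AJ	control	PSTAT3	1.00	ratio
AJ	control	PKCD	1.00	ratio
AJ	control	GPX	1.00	ratio
AJ	control	PLA2	1.00	ratio
AJ	control	ALOX5AP	1.00	ratio
AJ	control	ALOX15	1.00	ratio
AJ	control	PERK	1.00	ratio
AJ	control	PC	269.00	uM
AJ	ddc	PTGS1	2.13	ratio
AJ	ddc	ALOX5	1.00	ratio
AJ	ddc	PTGDS	1.00	ratio
AJ	ddc	PSTAT3	1.41	ratio
AJ	ddc	PKCD	4.30	ratio
AJ	ddc	GPX	6.51	ratio
AJ	ddc	PLA2	1.90	ratio
AJ	ddc	ALOX5AP	4.81	ratio
AJ	ddc	ALOX15	1.00	ratio
AJ	ddc	PERK	1.90	ratio
AJ	ddc	PC	206.00	uM
B6	control	PTGS1	1.00	ratio
B6	control	ALOX5	1.00	ratio
B6	control	PTGDS	1.00	ratio
B6	control	PSTAT3	1.00	ratio
B6	control	PKCD	1.00	ratio
B6	control	GPX	1.00	ratio
B6	control	PLA2	1.00	ratio
B6	control	ALOX5AP	1.00	ratio
B6	control	ALOX15	1.00	ratio
B6	control	PERK	1.00	ratio
B6	control	PC	249.00	uM
B6	ddc	PTGS1	1.41	ratio
B6	ddc	ALOX5	1.00	ratio
B6	ddc	PTGDS	1.00	ratio
B6	ddc	PSTAT3	1.42	ratio
B6	ddc	PKCD	4.48	ratio
B6	ddc	GPX	11.70	ratio
B6	ddc	PLA2	2.09	ratio
B6	ddc	ALOX5AP	6.30	ratio
B6	ddc	ALOX15	1.00	ratio
B6	ddc	PERK	2.09	ratio
B6	ddc	PC	209.00	uM
PWD	control	PTGS1	1.00	ratio
PWD	control	ALOX5	1.00	ratio
PWD	control	PTGDS	1.00	ratio
PWD	control	PSTAT3	1.00	ratio
PWD	control	PKCD	1.00	ratio
PWD	control	GPX	1.00	ratio
PWD	control	PLA2	1.00	ratio
PWD	control	ALOX5AP	1.00	ratio
PWD	control	ALOX15	1.00	ratio
PWD	control	PERK	1.00	ratio
PWD	control	PC	266.00	uM
PWD	ddc	PTGS1	2.09	ratio
PWD	ddc	ALOX5	1.00	ratio
PWD	ddc	PTGDS	1.00	ratio
PWD	ddc	PSTAT3	2.03	ratio
PWD	ddc	PKCD	3.85	ratio
PWD	ddc	GPX	19.42	ratio
PWD	ddc	PLA2	1.98	ratio
PWD	ddc	ALOX5AP	14.23	ratio
PWD	ddc	ALOX15	1.00	ratio
PWD	ddc	PERK	1.98	ratio
PWD	ddc	PC	255.00	uM
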