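# Functional-category distribution of dehydration-responsive gene classes
# reported by the reference A. thaliana repeated-dehydration study.
# Columns are the eight responding classes; values are gene counts.
category	PP	MM	PM	MP	PE	ME	EP	EM
Ribosomal and protein synthesis	1	31	1	0	10	135	2	26
Response to salt	25	8	84	14	154	55	35	24
Response to cold/heat	28	18	53	19	147	72	40	46
Response to ABA	24	6	80	12	143	38	39	24
LEA	12	0	4	2	9	2	5	0
Response to light	18	25	28	24	68	101	47	27
Circadian rhythm	1	1	13	6	11	23	8	12
Chloroplast	12	75	20	22	48	203	26	75
Thylakoid membrane	0	53	6	9	14	177	7	22
Membrane	30	23	106	41	312	233	73	71
TM transport, porins	20	6	62	26	138	95	50	24
Wall/PM	13	25	30	22	48	129	38	37
Kinases, receptors, signal transduction	4	16	52	31	107	111	25	21
Response to auxin	9	5	43	10	66	48	12	12
Response to ethylene	4	3	53	8	87	24	12	8
Response to GA	2	5	10	7	13	18	13	5
Response to JA	7	16	121	19	89	46	13	21
Response to SA	4	5	41	13	63	24	14	12
Transcription factors	29	6	73	25	161	100	51	22
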