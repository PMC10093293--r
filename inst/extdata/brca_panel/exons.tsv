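gene	label	ordinal	in_canonical
BRCA1	1	1	TRUE
BRCA1	2	2	TRUE
BRCA1	3	3	TRUE
BRCA1	5	4	TRUE
BRCA1	5q	5	FALSE
BRCA1	6	6	TRUE
BRCA1	7	7	TRUE
BRCA1	8	8	TRUE
BRCA1	8p	9	FALSE
BRCA1	9	10	TRUE
BRCA1	10	11	TRUE
BRCA1	11	12	TRUE
BRCA1	11q	13	FALSE
BRCA1	12	14	TRUE
BRCA1	13	15	TRUE
BRCA1	13p	16	FALSE
BRCA1	14	17	TRUE
BRCA1	14q	18	FALSE
BRCA1	15	19	TRUE
BRCA1	16	20	TRUE
BRCA1	17	21	TRUE
BRCA1	18	22	TRUE
BRCA1	19	23	TRUE
BRCA1	20	24	TRUE
BRCA1	21	25	TRUE
BRCA1	22	26	TRUE
BRCA1	23	27	TRUE
BRCA1	24	28	TRUE
BRCA2	1	1	TRUE
BRCA2	2	2	TRUE
BRCA2	3	3	TRUE
BRCA2	3q	4	FALSE
BRCA2	4	5	TRUE
BRCA2	5	6	TRUE
BRCA2	6	7	TRUE
BRCA2	6q	8	FALSE
BRCA2	7	9	TRUE
BRCA2	8	10	TRUE
BRCA2	9	11	TRUE
BRCA2	10	12	TRUE
BRCA2	11	13	TRUE
BRCA2	12	14	TRUE
BRCA2	12p	15	FALSE
BRCA2	13	16	TRUE
BRCA2	14	17	TRUE
BRCA2	15	18	TRUE
BRCA2	16	19	TRUE
BRCA2	17	20	TRUE
BRCA2	18	21	TRUE
BRCA2	19	22	TRUE
BRCA2	20	23	TRUE
BRCA2	20q	24	FALSE
BRCA2	21	25	TRUE
BRCA2	22	26	TRUE
BRCA2	23	27	TRUE
BRCA2	24	28	TRUE
BRCA2	25	29	TRUE
BRCA2	26	30	TRUE
BRCA2	27	31	TRUE
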