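sample_id	n_introgressed	n_lost	n_novel	n_reference
IL1	25	12	7	40
IL2	26	13	6	35
IL3	31	16	6	49
IL4	20	23	6	40
IL5	22	26	6	40
IL6	27	11	6	35
IL7	32	30	6	48
IL8	27	32	6	49
IL9	33	17	6	45
IL10	25	17	6	34
IL11	3	7	1	4
IL12	5	27	2	5
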