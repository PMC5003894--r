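sample_id	n_hyper	n_hypo
IL1	42	7
IL2	36	9
IL3	35	8
IL4	39	22
IL5	28	18
IL6	32	17
IL7	38	12
IL8	28	10
IL9	34	8
IL10	42	22
IL11	40	20
IL12	36	13
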