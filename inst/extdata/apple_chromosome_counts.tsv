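chromosome	n_rgas	n_singletons	n_clusters
Chr1	43	10	7
Chr2	109	14	15
Chr3	47	12	11
Chr4	27	12	6
Chr5	48	11	11
Chr6	9	2	2
Chr7	57	4	11
Chr8	76	11	14
Chr9	40	7	10
Chr10	56	14	14
Chr11	79	7	10
Chr12	37	11	6
Chr13	17	9	4
Chr14	22	6	4
Chr15	58	14	14
Chr16	14	3	4
Chr17	39	9	8
unanchored	90	0	0
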