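gene_id	s1	s2	s3	s4
g1	2	2	0	0
g2	2	4	0	2
g3	5	5	5	5
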