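# Constructed from biom file
#OTU ID	s1	s2	s3
ASV0001	10	0	3
ASV0002	0	5	7
ASV0003	2	2	2
ASV0004	0	0	11
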