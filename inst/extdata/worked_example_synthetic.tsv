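gene_id	n	folded	sfs_n	sfs_s	dn	ds	mn	ms
worked_example	20	FALSE	5,2,2,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0	4,2,3,2,2,1,1,1,0,0,0,0,0,0,1,0,0,0,0	15	8	500	200
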