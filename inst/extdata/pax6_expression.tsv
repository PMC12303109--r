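# Reciprocal expression of the two Drosophila Pax6 paralogues in Kc and S2 cells
# (published read counts, TPM, fold difference and log2 ratio; rank within the
#  significantly up/down TF gene sets comes from the authors' prior replicate study)
gene	gene_symbol	gene_id	kc_reads	s2_reads	fold_difference	kc_tpm	s2_tpm	log2_kc_s2	rank
eyeless	ey	43812	2	120	60	0.05	2.8	-5.8	7/66 down
twin of eyeless	toy	43833	773	6	128.83	21.78	0.19	6.83	7/57 up
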