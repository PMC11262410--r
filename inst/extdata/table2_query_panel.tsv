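gene_symbol	fbgn_id
Lac	FBgn0010238
Pdi	FBgn0286818
nrv2	FBgn0015777
Lost	FBgn0263594
Flo-2	FBgn0264078
alpha-Cat	FBgn0010215
Vha55	FBgn0005671
Atpalpha	FBgn0002921
Nrg	FBgn0264975
Cip4	FBgn0035533
Nrx-IV	FBgn0013997
gs2	FBgn0001145
shot	FBgn0013733
kst	FBgn0004167
sdk	FBgn0021764
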