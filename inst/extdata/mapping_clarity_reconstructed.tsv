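# signature <-> flow-phenotype mapping, three-arm trial cohort (26 pairs: 9 SVR + 17 ssGSEA).
# RECONSTRUCTED: the published analysis reports only the pair counts and worked
# examples (e.g. the pan-T CD3+ count mapped to specialised T-cell signatures);
# this table is a synthetic reconstruction consistent with those counts, built
# from the nine available flow phenotypes. It is a fixture for exercising the
# mapping machinery, not a transcription of a published table.
signature_id	flow_phenotype
cibersort.NK.cells.resting	NK.CD16.CD56.rWBC
cibersort.NK.cells.activated	NK.CD16.CD56.rWBC
cibersort.B.cells.naive	B.CD19.rWBC
cibersort.B.cells.memory	B.CD19.rWBC
cibersort.T.cells.CD8	CD8.T.rWBC
cibersort.T.cells.CD4.naive	NAIVE.CD4.CD45RA.rWBC
cibersort.T.cells.CD4.memory.resting	MEMORY.CD4.CD45RO.rWBC
cibersort.T.cells.CD4.memory.activated	MEMORY.CD4.CD45RO.rWBC
cibersort.T.cells.regulatory.Tregs	PAN.T.CD3.rWBC
xcell.B.cells	B.CD19.rWBC
xcell.Naive.B.cells	B.CD19.rWBC
xcell.Memory.B.cells	B.CD19.rWBC
xcell.Class.switched.memory.B.cells	B.CD19.rWBC
xcell.pro.B.cells	B.CD19.rWBC
xcell.CD4.T.cells	CD4.T.rWBC
xcell.CD4.naive.T.cells	NAIVE.CD4.CD45RA.rWBC
xcell.CD4.memory.T.cells	MEMORY.CD4.CD45RO.rWBC
xcell.CD4.Tcm	MEMORY.CD4.CD45RO.rWBC
xcell.CD4.Tem	MEMORY.CD4.CD45RO.rWBC
xcell.CD8.T.cells	CD8.T.rWBC
xcell.CD8.naive.T.cells	NAIVE.CD8.CD45RA.rWBC
xcell.CD8.Tcm	MEMORY.CD8.CD45RO.rWBC
xcell.CD8.Tem	MEMORY.CD8.CD45RO.rWBC
xcell.NK.cells	NK.CD16.CD56.rWBC
xcell.Tgd.cells	PAN.T.CD3.rWBC
xcell.Tregs	PAN.T.CD3.rWBC
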