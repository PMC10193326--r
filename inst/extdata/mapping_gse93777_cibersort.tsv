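# signature <-> flow-phenotype mapping, GSE93777 cohort, SVR-method signatures (14 pairs)
signature_id	flow_phenotype
cibersort.B.cells.memory	B.CELL.rWBC
cibersort.B.cells.naive	B.CELL.rWBC
cibersort.Dendritic.cells.resting	DC.rWBC
cibersort.Eosinophils	EOSINOPHIL.rWBC
cibersort.Mast.cells.resting	BASOPHIL.rWBC
cibersort.Monocytes	MONOCYTE.rWBC
cibersort.Neutrophils	NEUTROPHIL.rWBC
cibersort.NK.cells.resting	NK.rWBC
cibersort.Plasma.cells	PLASMABLAST.rWBC
cibersort.T.cells.CD4.memory.resting	MEMORY.CD4.rWBC
cibersort.T.cells.CD4.naive	NAIVE.CD4.rWBC
cibersort.T.cells.CD8	CD8.T.rWBC
cibersort.T.cells.gamma.delta	GAMMA.DELTA.T.rWBC
cibersort.T.cells.regulatory.Tregs	TREG.rWBC
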