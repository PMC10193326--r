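# signature <-> flow-phenotype mapping, GSE93777 cohort, ssGSEA-method signatures (25 pairs)
signature_id	flow_phenotype
xcell.B.cells	B.CELL.rWBC
xcell.Basophils	BASOPHIL.rWBC
xcell.CD4.memory.T.cells	MEMORY.CD4.rWBC
xcell.CD4.naive.T.cells	NAIVE.CD4.rWBC
xcell.CD4.T.cells	CD4.T.rWBC
xcell.CD4.Tcm	MEMORY.CD4.rWBC
xcell.CD4.Tem	MEMORY.CD4.rWBC
xcell.CD8.naive.T.cells	NAIVE.CD8.rWBC
xcell.CD8.T.cells	CD8.T.rWBC
xcell.CD8.Tcm	MEMORY.CD8.rWBC
xcell.CD8.Tem	CD45RA.MEMORY.CD8.rWBC
xcell.cDC	MDC.rWBC
xcell.Class.switched.memory.B.cells	B.CELL.rWBC
xcell.DC	DC.rWBC
xcell.Eosinophils	EOSINOPHIL.rWBC
xcell.Memory.B.cells	B.CELL.rWBC
xcell.Monocytes	MONOCYTE.rWBC
xcell.Naive.B.cells	B.CELL.rWBC
xcell.Neutrophils	NEUTROPHIL.rWBC
xcell.NK.cells	NK.rWBC
xcell.NKT	NKT.rWBC
xcell.pDC	PDC.rWBC
xcell.Plasma.cells	PLASMABLAST.rWBC
xcell.Tgd.cells	GAMMA.DELTA.T.rWBC
xcell.Tregs	TREG.rWBC
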