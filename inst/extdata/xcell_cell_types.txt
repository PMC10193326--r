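# 64-type xCell cell-type inventory (names-only; dot-normalized)
aDC
Adipocytes
Astrocytes
B.cells
Basophils
CD4.memory.T.cells
CD4.naive.T.cells
CD4.T.cells
CD4.Tcm
CD4.Tem
CD8.naive.T.cells
CD8.T.cells
CD8.Tcm
CD8.Tem
cDC
Chondrocytes
Class.switched.memory.B.cells
CLP
CMP
DC
Endothelial.cells
Eosinophils
Epithelial.cells
Erythrocytes
Fibroblasts
GMP
Hepatocytes
HSC
iDC
Keratinocytes
ly.Endothelial.cells
Macrophages
Macrophages.M1
Macrophages.M2
Mast.cells
Megakaryocytes
Melanocytes
Memory.B.cells
MEP
Mesangial.cells
Monocytes
MPP
MSC
mv.Endothelial.cells
Myocytes
Naive.B.cells
Neurons
Neutrophils
NK.cells
NKT
Osteoblasts
pDC
Pericytes
Plasma.cells
Platelets
Preadipocytes
pro.B.cells
Sebocytes
Skeletal.muscle
Smooth.muscle
Tgd.cells
Th1.cells
Th2.cells
Tregs
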