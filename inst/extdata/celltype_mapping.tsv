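tool	tool_celltype	canonical	lineage	class
SGL	B cells naive	B_cells_naive	lymphoid	cell_type
SGL	B cells memory	B_cells_memory	lymphoid	cell_type
SGL	Plasma cells	Plasma_cells	lymphoid	cell_type
SGL	T cells CD8	T_cells_CD8	lymphoid	cell_type
SGL	T cells CD4 naive	T_cells_CD4_naive	lymphoid	cell_type
SGL	T cells CD4 memory resting	T_cells_CD4_memory_resting	lymphoid	cell_type
SGL	T cells CD4 memory activated	T_cells_CD4_memory_activated	lymphoid	cell_type
SGL	T cells follicular helper	T_cells_follicular_helper	lymphoid	cell_type
SGL	T cells regulatory (Tregs)	T_regs	lymphoid	cell_type
SGL	T cells gamma delta	T_cells_gamma_delta	lymphoid	cell_type
SGL	NK cells resting	NK_cells_resting	lymphoid	cell_type
SGL	NK cells activated	NK_cells_activated	lymphoid	cell_type
SGL	Monocytes	Monocytes	myeloid	cell_type
SGL	Macrophages M0	Macrophages_M0	myeloid	cell_type
SGL	Macrophages M1	Macrophages_M1	myeloid	cell_type
SGL	Macrophages M2	Macrophages_M2	myeloid	cell_type
SGL	Dendritic cells resting	Dendritic_cells_resting	myeloid	cell_type
SGL	Dendritic cells activated	Dendritic_cells_activated	myeloid	cell_type
SGL	Mast cells resting	Mast_cells_resting	myeloid	cell_type
SGL	Mast cells activated	Mast_cells_activated	myeloid	cell_type
SGL	Eosinophils	Eosinophils	myeloid	cell_type
SGL	Neutrophils	Neutrophils	myeloid	cell_type
NNLS	B cells naive	B_cells_naive	lymphoid	cell_type
NNLS	B cells memory	B_cells_memory	lymphoid	cell_type
NNLS	Plasma cells	Plasma_cells	lymphoid	cell_type
NNLS	T cells CD8	T_cells_CD8	lymphoid	cell_type
NNLS	T cells CD4 naive	T_cells_CD4_naive	lymphoid	cell_type
NNLS	T cells CD4 memory resting	T_cells_CD4_memory_resting	lymphoid	cell_type
NNLS	T cells CD4 memory activated	T_cells_CD4_memory_activated	lymphoid	cell_type
NNLS	T cells follicular helper	T_cells_follicular_helper	lymphoid	cell_type
NNLS	T cells regulatory (Tregs)	T_regs	lymphoid	cell_type
NNLS	T cells gamma delta	T_cells_gamma_delta	lymphoid	cell_type
NNLS	NK cells resting	NK_cells_resting	lymphoid	cell_type
NNLS	NK cells activated	NK_cells_activated	lymphoid	cell_type
NNLS	Monocytes	Monocytes	myeloid	cell_type
NNLS	Macrophages M0	Macrophages_M0	myeloid	cell_type
NNLS	Macrophages M1	Macrophages_M1	myeloid	cell_type
NNLS	Macrophages M2	Macrophages_M2	myeloid	cell_type
NNLS	Dendritic cells resting	Dendritic_cells_resting	myeloid	cell_type
NNLS	Dendritic cells activated	Dendritic_cells_activated	myeloid	cell_type
NNLS	Mast cells resting	Mast_cells_resting	myeloid	cell_type
NNLS	Mast cells activated	Mast_cells_activated	myeloid	cell_type
NNLS	Eosinophils	Eosinophils	myeloid	cell_type
NNLS	Neutrophils	Neutrophils	myeloid	cell_type
cibersort_abs	T cells CD8	T_cells_CD8	lymphoid	cell_type
cibersort_abs	B cells naive	B_cells_naive	lymphoid	cell_type
cibersort_abs	Macrophages M2	Macrophages_M2	myeloid	cell_type
ssGSEA	CD8 T cells	T_cells_CD8	lymphoid	cell_type
ssGSEA	B cells	B_cells_naive	lymphoid	cell_type
ssGSEA	Cytotoxic lymphocytes	Cytotoxic_Lymphocytes	lymphoid	cell_type
ssGSEA	Th17 cells	Th17_cells	lymphoid	cell_type
ssGSEA	Fibroblasts	Fibroblasts	stromal	cell_type
ssGSEA	Endothelial cells	Endothelial_cells	stromal	cell_type
ssGSEA	Pericytes	Pericytes	stromal	cell_type
ssGSEA	Adipocytes	Adipocytes	stromal	cell_type
ssGSEA	Hypoxia	Hypoxia	other	process
ssGSEA	Angiogenesis	Angiogenesis	other	process
mcp_counter	CD8 T cells	T_cells_CD8	lymphoid	cell_type
mcp_counter	Cytotoxic lymphocytes	Cytotoxic_Lymphocytes	lymphoid	cell_type
mcp_counter	Endothelial cells	Endothelial_cells	stromal	cell_type
mcp_counter	Fibroblasts	Fibroblasts	stromal	cell_type
xcell	CD8+ T-cells	T_cells_CD8	lymphoid	cell_type
xcell	Fibroblasts	Fibroblasts	stromal	cell_type
xcell	Endothelial cells	Endothelial_cells	stromal	cell_type
xcell	Pericytes	Pericytes	stromal	cell_type
xcell	Adipocytes	Adipocytes	stromal	cell_type
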