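# Cancer-hallmark Gene Ontology biological-process terms.
# Keyword-derived stand-in list for a curated cancer-relevant catalogue;
# replace with any one-column file of term identifiers (size is recorded
# in the run manifest).
GO:0006915  # apoptotic process
GO:0043066  # negative regulation of apoptotic process
GO:0043065  # positive regulation of apoptotic process
GO:0008283  # cell population proliferation
GO:0008284  # positive regulation of cell population proliferation
GO:0008285  # negative regulation of cell population proliferation
GO:0007049  # cell cycle
GO:0051726  # regulation of cell cycle
GO:0000082  # G1/S transition of mitotic cell cycle
GO:0007050  # cell cycle arrest
GO:0006281  # DNA repair
GO:0006974  # DNA damage response
GO:0001525  # angiogenesis
GO:0045766  # positive regulation of angiogenesis
GO:0016477  # cell migration
GO:0030335  # positive regulation of cell migration
GO:0007155  # cell adhesion
GO:0098609  # cell-cell adhesion
GO:0001837  # epithelial to mesenchymal transition
GO:0016055  # Wnt signaling pathway
GO:0060070  # canonical Wnt signaling pathway
GO:0000165  # MAPK cascade
GO:0043410  # positive regulation of MAPK cascade
GO:0048015  # phosphatidylinositol-mediated signaling
GO:0043491  # protein kinase B signaling
GO:0007173  # epidermal growth factor receptor signaling pathway
GO:0030522  # intracellular receptor signaling pathway
GO:0006955  # immune response
GO:0002418  # immune response to tumor cell
GO:0001906  # cell killing
GO:0001666  # response to hypoxia
GO:0071456  # cellular response to hypoxia
GO:0000723  # telomere maintenance
GO:0090398  # cellular senescence
GO:0006096  # glycolytic process
GO:0061621  # canonical glycolysis
GO:0006119  # oxidative phosphorylation
GO:0008152  # metabolic process
GO:0030155  # regulation of cell adhesion
GO:2000772  # regulation of cellular senescence
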