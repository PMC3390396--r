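# demo pipeline configuration: three genotypes, all analyses
# (small cell counts so the demo completes in seconds)
schema_version = 1
seed = 42
genotypes = WT, hei10, mer3hei10
n_cells.WT = 60
n_cells.hei10 = 60
n_cells.mer3hei10 = 60
analyses = gof, ttest, interference, coloc
coloc_tolerance = 0.01
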