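gene	n_individuals
COL4A1	6
L1CAM	3
KIF1A	3
MAOB	3
AGAP1	3
TUBA1A	2
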