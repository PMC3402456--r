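% Contradiction worked example: cladribine agonises PNP, which sits in
% a cancer-promoting bioprocess.
drug(cladribine).
protein(pnp).
interaction(cladribine, induces, pnp).
relation(pnp, is_associated, pos_reg_cell_proliferation).
cancer_promoting_bioprocess(pos_reg_cell_proliferation).
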