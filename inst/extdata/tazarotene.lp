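% Indirect-inference worked example: tazarotene / RARA / EGFR.
drug(tazarotene).
protein(rara).
protein(egfr).
interaction(tazarotene, induces, rara).
interaction(rara, inhibits, egfr).
oncogene(egfr).
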