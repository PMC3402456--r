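% Direct-inference worked example: dipyridamole / adenosine deaminase.
drug(dipyridamole).
protein(ada).
disease(cancer).
interaction(dipyridamole, inhibits, ada).
relation(overexpressed(ada), associated_with, cancer).
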