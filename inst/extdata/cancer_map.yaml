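target_class: cancer
members: []
patterns:
  - cancer
  - carcinoma
  - leukemia
  - lymphoma
  - tumor
  - tumour
  - melanoma
  - sarcoma
  - glioma
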