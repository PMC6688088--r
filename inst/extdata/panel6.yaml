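markers: [CD3, CD4, CD8, CD45RA, CCR7, CD38]
levels:
  - [CD3, CD4]
  - [CD8, CD45RA]
  - [CCR7, CD38]
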