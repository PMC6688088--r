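markers: [CD62L, CD27, IL22, IL17A]
levels:
  - [CD62L, CD27]
  - [IL22, IL17A]
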