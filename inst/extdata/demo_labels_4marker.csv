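Sample,group
A_01,A
A_02,A
A_03,A
B_01,B
B_02,B
B_03,B
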