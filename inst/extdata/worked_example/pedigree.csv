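"id","parent1","parent2"
"P1",,
"P2",,
"P3",,
"P4",,
"CHK1",,
"CHK2",,
"L11","P1","P2"
"L12","P1","P2"
"L13","P1","P2"
"L21","P3","P4"
"L22","P3","P4"
"L23","P3","P4"
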