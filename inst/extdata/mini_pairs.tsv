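g1	GO:0009593
g1	GO:0033554
g2	GO:0033554
g3	GO:0050896
g4	GO:0009593
g5	GO:0006950
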