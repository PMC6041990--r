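g1	O
g2	U
g3	N
g4	N
g5	N
g6	N
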