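# Tiny two-layer example multiplex: a 6-node social system with a
# collaboration layer (L1) and a communication layer (L2) sharing two edges.
[NODES]
f
[EDGES]
L1 a b
L1 b c
L1 c d
L1 a d
L2 a b
L2 c d
L2 d e
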