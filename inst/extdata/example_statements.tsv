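1	Statement about topic A
2	Statement about topic B
3	Statement about topic C
4	Statement about topic D
5	Statement about topic E
6	Statement about topic F
7	Statement about topic G
8	Statement about topic H
9	Statement about topic I
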