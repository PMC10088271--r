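# Example region configuration: the three-part layout of a Het-A-like GAG
# protein alignment (N-terminal fragment, central conserved core, C-terminal
# fragment), in 0-based half-open protein-alignment columns. Adjust the
# boundaries to your own alignment before use.
gag5	0	467
core	467	685
gag3	685	918
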