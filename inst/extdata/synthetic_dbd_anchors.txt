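# synthetic stand-in anchor set: nine 0-based DNA-contact positions
# within the 76-aa DBD seeds (configurable)
5
12
18
27
33
40
52
61
70
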