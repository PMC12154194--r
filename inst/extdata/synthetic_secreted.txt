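P0001
P0007
P0010
P0018
P0024
P0025
P0036
P0037
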