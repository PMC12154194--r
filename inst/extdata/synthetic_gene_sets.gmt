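planted_target_module	synthetic: module driven by the planted liver driver	P0003	P0004	P0005	P0013	P0021	P0026	P0027	P0028	P0032	P0038	P0039	P0040
decoy_random_set	synthetic: random decoy set	P0002	P0005	P0009	P0014	P0022	P0028	P0033	P0039
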