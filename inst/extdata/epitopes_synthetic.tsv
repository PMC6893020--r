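name	start	end
epitope_A	50	64
epitope_B	58	72
epitope_C	95	109
epitope_D	140	154
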