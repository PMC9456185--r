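replicate,t_delta_s
1,-24.12
2,-24.12
3,-24.12
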