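country,window_start,window_end
AA,2000,2010
BB,2005,
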