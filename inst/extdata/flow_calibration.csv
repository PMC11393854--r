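count,percent
39940,2.5
18588,0.98
316,0.019
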