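allofep: bad --transition '0-' (want label:site1,site2[|msite1,...])
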