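cost,j1,j2,j3
i1,2,4,1
i2,1,2,3
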