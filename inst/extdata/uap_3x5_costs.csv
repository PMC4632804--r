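cost,j1,j2,j3,j4,j5
i1,5,9,1,2,7
i2,9,8,6,4,4
i3,4,7,8,5,2
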