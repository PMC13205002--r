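id,sex,age,height,weight
S1,M,25,177,72
S2,M,26,178,81
S3,M,24,173,60
S4,M,25,175,80
S5,M,27,174,64
S6,M,25,178,82
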