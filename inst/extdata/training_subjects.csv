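id,sex,age,height,weight
T1,M,24,176,70
T2,F,22,165,55
T3,F,22,167,50
T4,M,25,175,79
T5,M,25,180,80
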