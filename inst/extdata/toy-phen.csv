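ID,PED,AGE,SEX,DBP,SBP,MED
sampleA,FAM1,45,M,82,128,0
sampleB,FAM1,51,F,93,146,1
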