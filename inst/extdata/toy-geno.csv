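chrom,pos,ref,alt,sampleA,sampleB
1,10100,A,G,AA,AG
1,20200,C,T,CT,TT
1,30300,G,A,GG,NN
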