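design,set,side,adapter_enzyme,overhang,post,polarity
1,R1.A,read1,NheI,CTAG,G,five_prime
1,R2.1,read2,EcoRI,AATT,T,five_prime
2,R1.B,read1,ClaI,CG,AT,five_prime
2,R2.2,read2,BamHI,GATC,C,five_prime
3,R1.C,read1,PstI,TGCA,CTGCA,three_prime
3,R2.3,read2,DdeI,TNA,G,five_prime
4,R1.D,read1,CviQI,TA,G,five_prime
4,R2.4,read2,HindIII,AGCT,T,five_prime
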