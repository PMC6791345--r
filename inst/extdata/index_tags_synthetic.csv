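side,version,tag,source
read1,A,CCGAAT,published
read1,B,TTAGGCA,published
read1,C,AACTCGTC,published
read1,D,GGTCTACGT,published
read1,E,ACTGTA,synthetic
read1,F,TGAGCCC,synthetic
read1,G,GCCGTAGT,synthetic
read1,H,TTAGAAACG,synthetic
read2,1,CTAACG,published
read2,2,TCGGTAC,published
read2,3,GATCGTTG,published
read2,4,AGCTACACT,published
read2,5,AGGATC,synthetic
read2,6,TGGTCAA,synthetic
read2,7,GGGTAGGA,synthetic
read2,8,CATTCATAG,synthetic
read2,9,GACGAA,synthetic
read2,10,TTTATCG,synthetic
read2,11,CTATGTAG,synthetic
read2,12,CAATCTATA,synthetic
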