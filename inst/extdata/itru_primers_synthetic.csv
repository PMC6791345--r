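name,side,sequence
iTru5_01_synth,i5,TACCGCTA
iTru5_02_synth,i5,ACTTATAG
iTru5_03_synth,i5,AATTGATA
iTru5_04_synth,i5,GGCGCGAG
iTru5_05_synth,i5,TTGAGTAT
iTru5_06_synth,i5,GATAAGTG
iTru5_07_synth,i5,AATGGTGA
iTru5_08_synth,i5,CTAATAAA
iTru5_09_synth,i5,GGGACCTG
iTru5_10_synth,i5,TGTACTTC
iTru5_11_synth,i5,CCTGGGTC
iTru5_12_synth,i5,ACCACCGT
iTru5_13_synth,i5,GCGTCGGT
iTru5_14_synth,i5,CAACAAGT
iTru5_15_synth,i5,CGACACGC
iTru5_16_synth,i5,AATTCCGT
iTru7_01_synth,i7,GCTTAAGG
iTru7_02_synth,i7,GCCCCAAA
iTru7_03_synth,i7,ATCACCCC
iTru7_04_synth,i7,CGCACAAC
iTru7_05_synth,i7,ACCGTACA
iTru7_06_synth,i7,CGGCATAC
iTru7_07_synth,i7,AGCTGGCA
iTru7_08_synth,i7,CGTTCCTG
iTru7_09_synth,i7,TCGTTAAG
iTru7_10_synth,i7,TGAAGCAT
iTru7_11_synth,i7,AAAGCACT
iTru7_12_synth,i7,TGGGACTA
iTru7_13_synth,i7,CTAATGAC
iTru7_14_synth,i7,CCGTAAGA
iTru7_15_synth,i7,GAGGCTAC
iTru7_16_synth,i7,TATGCTTA
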