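design,side,version,tag,reason
2,read2,5,CATACA,universal index 5 creates a BamHI recognition site in the assembled Design 2 Read 2 adapter
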