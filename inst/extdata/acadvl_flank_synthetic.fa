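>acadvl_promoter_flank_synthetic snp at position 21, ref T, alt C
GATCGGATAGCTAGACACCTTAGGATCGATCGGATAGCATG
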