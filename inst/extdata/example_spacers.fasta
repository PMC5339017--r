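>cts1_synthetic synthetic stand-in guide for the EYFP reporter site
GGTCGACCTCGAGTCAGTCA
>cts2_synthetic synthetic stand-in guide for the ECFP reporter site
GGCACTGCGGCTGGAGGTGG
>demo3 mixed-composition demo guide
GATGGGTGCGATCGATGCAG
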