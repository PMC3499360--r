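# A/T-rich promoter motif, one row per position: A C G T probabilities
0.88 0.04 0.04 0.04
0.88 0.04 0.04 0.04
0.04 0.04 0.04 0.88
0.88 0.04 0.04 0.04
0.88 0.04 0.04 0.04
0.04 0.04 0.04 0.88
0.04 0.04 0.04 0.88
0.88 0.04 0.04 0.04
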