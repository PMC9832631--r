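mic,cumulative_fraction
0.0625,0.011
0.125,0.047
0.25,0.182
0.5,0.5
1,0.818
2,0.953
4,0.989
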