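time_s,adp_uM
0,0
300,42
600,84
900,126
1200,168
1500,210
1800,252
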