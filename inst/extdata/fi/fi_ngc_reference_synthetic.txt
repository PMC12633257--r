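# synthetic reference f-I table (reduced model at fitted
# geometry); columns: amplitude_nA frequency_hz
0 0
0.025 0
0.05 0
0.075 38.6
0.1 56.6
0.125 68.2
0.15 77.2
0.175 84.6
0.2 90.8
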