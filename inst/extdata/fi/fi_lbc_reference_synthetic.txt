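# synthetic reference f-I table (reduced model at fitted
# geometry); columns: amplitude_nA frequency_hz
0 0
0.1 0
0.2 43.8
0.3 80
0.4 94.8
0.5 105.4
0.6 114
0.7 121
0.8 127.2
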