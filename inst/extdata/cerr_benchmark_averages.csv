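algorithm,z,n_apertures,beam_on_time
rVNS,48.63,19,77.2
VND12,50.4,16,81.2
VND21,49.41,18,78.0
LS,49.33,19,77.3
sequential_fmo,42.85,NA,NA
sequential_r1,44.24,142,217
sequential_r2,48.57,92,214
sequential_r4,68.45,51,220
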