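freq_khz,threshold_db,kind
1,98,masked_AEP
4,95,masked_AEP
10,92,masked_AEP
20,88,masked_AEP
32,86,masked_AEP
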