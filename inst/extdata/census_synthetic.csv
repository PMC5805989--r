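age_group,population_count
0-5,5200
6-19,13800
20-39,30300
40-64,37800
65+,12900
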