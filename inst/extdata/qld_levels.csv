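level,n_areas,mean_count,median_count,total_cases
mesh,67047,0.3,0.27,20700
sa1,11507,1.9,1.7,20700
sa2,507,39.6,33.0,20700
sa3,82,252.4,223.4,20700
sa4,19,1089.4,972.0,20700
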