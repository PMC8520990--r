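participant,pair_level_db,masker_freq_khz,masker_level_db,precursor,mean_db,sd_db,n_runs
P1,65,2.4,65,none,23.53,1.60,2
P1,65,4,16,none,22.97,0.20,2
P1,65,2.4,65,tone_4khz_40db,33.17,0.24,2
P1,65,4,16,tone_4khz_40db,27.67,0.94,2
P1,75,2.4,75,none,30.20,4.53,2
P1,75,4,33,none,29.98,1.21,2
P1,75,2.4,75,tone_4khz_40db,40.42,3.24,2
P1,75,4,33,tone_4khz_40db,35.85,0.68,2
P2,65,2.4,65,none,28.65,1.09,4
P2,65,4,21,none,33.85,11.54,4
P2,65,2.4,65,tone_4khz_40db,50.80,2.90,4
P2,65,4,21,tone_4khz_40db,36.42,1.89,4
P2,80,2.4,80,none,45.41,4.59,4
P2,80,4,45,none,51.68,5.56,4
P2,80,2.4,80,tone_4khz_40db,68.36,9.77,4
P2,80,4,45,tone_4khz_40db,57.89,2.31,4
P3,75,2.4,75,none,25.25,1.06,2
P3,75,4,14,none,22.30,0.42,2
P3,75,2.4,75,tone_4khz_40db,52.40,7.07,2
P3,75,4,14,tone_4khz_40db,26.27,0.09,2
P3,80,2.4,80,none,31.61,1.15,2
P3,80,4,30,none,29.72,0.08,2
P3,80,2.4,80,tone_4khz_40db,50.77,2.27,2
P3,80,4,30,tone_4khz_40db,35.16,0.79,2
P4,75,2.4,75,none,29.93,1.52,2
P4,75,4,28,none,30.76,1.28,2
P4,75,2.4,75,tone_4khz_40db,45.60,1.98,2
P4,75,4,28,tone_4khz_40db,39.24,4.38,2
P4,80,2.4,80,none,36.18,1.44,2
P4,80,4,37,none,41.81,3.37,2
P4,80,2.4,80,tone_4khz_40db,48.46,0.94,2
P4,80,4,37,tone_4khz_40db,43.93,3.21,2
P5,65,2.4,65,none,27.12,3.84,2
P5,65,4,21,none,26.08,4.36,2
P5,65,2.4,65,tone_4khz_40db,43.48,2.17,3
P5,65,4,21,tone_4khz_40db,32.19,0.04,2
P5,75,2.4,75,none,28.89,1.97,2
P5,75,4,27,none,29.78,1.96,2
P5,75,2.4,75,tone_4khz_40db,46.78,1.96,2
P5,75,4,27,tone_4khz_40db,33.54,0.05,2
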