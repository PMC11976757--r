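subject_id,cvr_mca,cvr_aca,cvr_lesion_mean,cvr_lesion_sd,lesion_ml,steal_aca_mca_ml,steal_in_lesion_ml,steal_outside_ml
1,0.07,0.11,0.04,0.01,10.18,14.94,3.84,11.09
2,0.09,0.07,0.02,0.01,14.58,42.64,6.42,36.22
3,0.08,0.14,0.06,0.01,47.15,4.40,0.70,3.70
4,0.11,0.09,0.08,0.01,2.02,2.71,0.06,2.65
5,0.06,0.08,0.01,0.01,97.12,189.76,73.84,115.92
6,-0.03,-0.01,-0.03,0.02,117.29,174.03,73.75,100.28
7,0.08,0.06,-0.03,0.02,72.13,129.37,45.88,83.49
8,0.08,0.06,0.06,0.01,26.30,8.77,1.24,7.54
9,0.12,0.08,0.04,0.01,13.89,4.07,1.34,2.73
10,0.14,0.12,0.08,0.01,4.29,2.59,0.00,2.60
11,0.19,0.23,0.09,0.02,18.00,21.58,2.79,18.78
12,0.15,0.20,0.03,0.03,36.41,42.69,19.34,23.35
13,0.08,0.08,-0.01,0.01,89.57,83.99,51.79,32.20
14,0.06,0.00,0.03,0.01,17.74,25.79,3.28,22.51
15,0.20,0.14,0.17,0.02,1.33,0.36,0.00,0.36
16,0.06,0.15,-0.05,0.01,52.84,113.19,46.55,66.64
17,0.04,0.05,-0.04,0.02,23.30,57.50,17.92,39.57
18,0.13,0.10,0.08,0.01,30.78,18.49,4.97,13.52
19,0.18,0.13,0.13,0.02,16.18,9.51,2.11,7.40
20,0.11,0.10,0.05,0.01,80.20,33.94,21.05,12.89
21,0.14,0.12,0.08,0.01,30.30,4.08,0.59,3.49
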