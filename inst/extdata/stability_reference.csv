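subject,method,repeatability_pct,prob_mean,prob_sd
1,averaged_baseline,68,0.561,0.098
2,averaged_baseline,76,0.632,0.119
3,averaged_baseline,100,0.732,0.090
4,averaged_baseline,54,0.500,0.059
5,averaged_baseline,98,0.735,0.112
6,averaged_baseline,100,0.672,0.090
7,averaged_baseline,84,0.603,0.100
8,averaged_baseline,56,0.567,0.082
9,averaged_baseline,70,0.689,0.130
10,averaged_baseline,76,0.629,0.140
1,frame_gmm,100,0.460,0.016
2,frame_gmm,100,0.434,0.039
3,frame_gmm,98,0.406,0.027
4,frame_gmm,100,0.397,0.025
5,frame_gmm,100,0.451,0.031
6,frame_gmm,70,0.381,0.020
7,frame_gmm,82,0.362,0.013
8,frame_gmm,76,0.381,0.013
9,frame_gmm,90,0.384,0.019
10,frame_gmm,100,0.408,0.017
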