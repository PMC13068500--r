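area,peak_elevation,peak_strength,gam_r2,gam_p_printed,brt_rmse,brt_mae,brt_r2
0.0001,2351.8,Weak,0.067,0.217,0.746,0.602,0.242
0.01,2380.6,Weak,0.123,0.082,1.894,1.579,0.030
0.25,2411.7,Strong,0.191,0.016,2.390,1.934,0.270
1,2429.1,Strong,0.311,0.001,1.992,1.644,0.690
25,NA,NA,0.396,<0.001,2.180,1.677,0.794
100,NA,NA,0.408,<0.001,2.424,1.709,0.785
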