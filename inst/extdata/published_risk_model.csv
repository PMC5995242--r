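variable,B,SE,Wald,p,ExpB
rel_sa_pct_small_cap,-2.173,0.810,7.197,0.007,0.114
width_intermediate_cap,-1.706,0.810,4.435,0.035,0.182
rel_sa_pct_intermediate_cap,-1.778,0.687,6.700,0.010,5.916
rel_density_intermediate_cap,0.966,0.537,3.23,0.072,2.628
width_large_cap,-1.644,0.652,6.349,0.012,0.193
roundness_large_cap,-1.404,0.508,7.644,0.006,4.072
rel_density_large_cap,-1.310,0.647,4.096,0.043,0.270
branching_total,-1.509,0.646,5.454,0.020,0.221
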