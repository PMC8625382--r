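analyte,temperature_C,k_per_min,k_sd,r2,t_half_min,t_half_sd,d_min,d_sd
TAC,75,0.0069,0.0008,0.96,100.32,1.91,333.33,6.85
TAC,95,0.0138,0.0021,0.96,50.16,1.42,166.67,4.68
TAC,115,0.0253,0.0083,0.98,27.36,0.93,90.91,3.45
TAC,135,0.0737,0.0133,0.98,9.41,0.72,31.25,2.06
TAC,155,0.1865,0.0236,0.98,3.72,0.48,12.35,1.08
antioxidant_activity,75,0.0048,0.0027,0.92,143.32,2.42,476.19,10.31
antioxidant_activity,95,0.0069,0.0042,0.93,100.33,2.51,333.33,9.57
antioxidant_activity,115,0.0085,0.0064,0.93,81.34,1.82,270.27,8.67
antioxidant_activity,135,0.0104,0.0075,0.98,66.88,1.74,222.22,7.48
antioxidant_activity,155,0.0133,0.0084,0.99,51.89,1.46,172.41,6.12
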