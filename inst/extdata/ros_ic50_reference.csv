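enzyme,sample,ic50_ug_mL,sd,n,letter
alpha_amylase,extract,1.02,0.30,3,a
alpha_amylase,acarbose,4.49,0.44,3,b
alpha_glucosidase,extract,0.57,0.16,3,a
alpha_glucosidase,acarbose,2.09,0.14,3,b
lipase,extract,4.57,0.86,3,a
lipase,orlistat,3.18,0.33,3,a
LOX,extract,2.40,0.71,3,a
LOX,quercetin,1.95,0.20,3,a
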