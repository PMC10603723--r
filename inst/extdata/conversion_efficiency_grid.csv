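temperature_C,weight_class_g,e_g,determined
10,30,33.7,TRUE
10,50,35.01,TRUE
10,70,33.56,TRUE
10,90,31.29,TRUE
10,110,29.06,FALSE
10,130,26.93,FALSE
10,150,25.15,TRUE
10,170,24.02,FALSE
14,30,20.52,FALSE
14,50,22.06,FALSE
14,70,20.25,FALSE
14,90,19.33,FALSE
14,110,18.01,FALSE
14,130,17.4,FALSE
14,150,14.98,FALSE
14,170,14.11,FALSE
18,30,14.2,TRUE
18,50,16.03,TRUE
18,70,14.11,TRUE
18,90,12.97,FALSE
18,110,12.31,TRUE
18,130,12.19,TRUE
18,150,9.72,TRUE
18,170,8.97,TRUE
22,30,19.48,FALSE
22,50,21.5,FALSE
22,70,19.12,FALSE
22,90,15.92,FALSE
22,110,14.29,FALSE
22,130,14.14,FALSE
22,150,12.61,FALSE
22,170,11.69,FALSE
26,30,31.8,FALSE
26,50,34.22,TRUE
26,70,31.76,TRUE
26,90,24.33,TRUE
26,110,21.5,FALSE
26,130,20.23,TRUE
26,150,20.44,FALSE
26,170,19.21,TRUE
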