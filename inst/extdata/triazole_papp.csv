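compound,accumulation_percent,papp_1e6_cm_s,papp_sd_1e6_cm_s,relative_papp
amoxicillin,0,6.5,0.2,0.16
0594,24,11.5,2.6,0.30
0595,79,3.0,0.4,0.08
0596,12,24.4,2.7,0.63
0599,22,18.4,1.1,0.47
0600,66,7.9,1.0,0.20
0618,56,7.1,0.2,0.18
antipyrine,0,38.9,3.0,1.00
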