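compound,bmc_d50_uM,corrected_bmc_d50_uM
0594,6.9,23.3
0595,11.0,141.8
0596,11.4,18.1
0599,1.8,3.8
0600,4.2,21.0
0618,4.3,23.7
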