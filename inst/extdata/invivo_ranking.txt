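# In vivo developmental-toxicity ranking of the six triazole test
# compounds (expert assessment of the rat prenatal studies), most toxic
# first.
0599
0596
0600
0594
0618
0595
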