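{"bases":[[[21.3532405967269,16.9840793071537,-21.9221387210876],[-39.5833476639167,17.1750458477942,-12.7740513480911],[-0.50555526904676,43.3705621982016,41.457674180806]]],"labels":[1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,0,0,0],"noise_sigma":0.000167755958737403,"cell":[35,45,60,85,95,100],"seed":42}
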