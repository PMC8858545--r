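# lineshape: lorentzian
"metabolite","center_ppm","amplitude","linewidth_ppm"
"NAA",2.008,3,0.035
"Cr",3.027,3,0.035
"Cr",3.913,2,0.035
"GABA",1.889,2,0.035
"GABA",2.284,2,0.035
"GABA",3.012,2,0.035
"Glu",2.12,1,0.035
"Glu",2.35,1,0.035
"Glu",3.746,1,0.035
"Ins",3.52,2,0.035
"Ins",3.614,2,0.035
"Lac",1.313,3,0.035
"Lac",4.099,1,0.035
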