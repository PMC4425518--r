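distance_lo,distance_hi,cc_lo,cc_hi,source
0,50,10,15,paired whole-cell recordings (reported range)
150,200,4,6,paired whole-cell recordings (reported value ~5%)
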