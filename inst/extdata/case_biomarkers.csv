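cycle,label,marker,value,units
0,baseline,PSA,154.2,ug/L
1,post_cycle1,PSA,24.6,ug/L
4,week6_post_cycle4,PSA,1.05,ug/L
6,post_cycle6,PSA,0.26,ug/L
0,baseline,MTV,160.3,mL
4,week6_post_cycle4,MTV,4.1,mL
6,post_cycle6,MTV,1.27,mL
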