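cycle,LLN,DLN1,DLN2,B1,B2,B3
1,6.89,25.57,6.8,5.55,6.25,3.75
2,6.03,9.43,3.04,0.64,1.85,1.96
3,2.84,8.3,2.59,0.48,0.97,1.86
4,2.72,7.24,2.91,N/A,N/A,N/A
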