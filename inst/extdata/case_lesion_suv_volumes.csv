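cycle,lesion,volume_ml,suvmax_4h,suvmax_24h,suvmax_48h
1,LLN,0.67,2.69,2.64,2.06
1,DLN1,3.9,33.56,14.36,9.8
1,DLN2,0.6,24.73,11.2,8.9
1,B1,1.5,9.5,4.21,2.61
1,B2,0.4,5.72,2.33,1.56
1,B3,0.3,2.9,0.96,0.66
2,LLN,0.37,1.14,0.73,0.68
2,DLN1,1.22,5.73,2.28,1.43
2,DLN2,0.4,3.56,1.56,1.28
2,B1,1.5,1.83,0.92,0.64
2,B2,0.4,1.23,0.42,0.29
2,B3,0.3,1.32,0.27,0.15
3,LLN,0.1,N/A,N/A,N/A
3,DLN1,0.82,3.12,1.19,0.76
3,DLN2,0.26,N/A,0.94,N/A
3,B1,1.5,1.02,0.52,0.35
3,B2,0.4,N/A,N/A,N/A
3,B3,0.3,N/A,N/A,N/A
4,LLN,0.1,N/A,N/A,N/A
4,DLN1,0.5,1.96,0.79,0.52
4,DLN2,0.13,N/A,0.5,N/A
4,B1,1.5,0.66,0.32,0.22
4,B2,0.4,N/A,N/A,N/A
4,B3,0.3,N/A,N/A,N/A
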