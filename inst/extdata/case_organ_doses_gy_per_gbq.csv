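cycle,method,right_kidney,left_kidney,liver,spleen,parotid_glands,submandibular_glands,lacrimal_glands
1,voxel,0.31,0.30,0.03,0.01,0.11,0.24,0.80
1,mird,0.36,0.35,0.03,0.03,N/A,N/A,N/A
2,voxel,0.39,0.35,0.03,0.03,0.12,0.20,0.51
2,mird,0.42,0.40,0.04,0.04,N/A,N/A,N/A
3,voxel,0.37,0.34,0.03,0.03,0.11,0.04,0.37
3,mird,0.40,0.39,0.04,0.03,N/A,N/A,N/A
4,voxel,0.43,0.36,0.04,0.05,0.12,0.21,0.30
4,mird,0.47,0.42,0.05,0.05,N/A,N/A,N/A
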