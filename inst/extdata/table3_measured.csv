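donor,acceptor,position,efficiency,se,significance,rel_distance_printed,rel_distance_se_printed,r_printed,r_se_printed
Agp2,S122C,122,0.09,0.02,ab,1.47,0.04,73,2
Agp2,A362C,362,0.10,0.02,,1.45,0.04,72,3
Agp2,K517C,517,0.15,0.04,,1.34,0.05,67,3
Agp2,R535C,535,0.21,0.02,a,1.24,0.03,62,2
Agp2,K554C,554,0.28,0.06,b,1.17,0.05,58,3
Agp2,R603C,603,0.20,0.03,,1.26,0.03,63,2
Agp2,A362C-PCM,362,0.00,0.03,**,NA,NA,NA,NA
Agp2-PCM,K517C,517,0.14,0.03,,1.35,0.05,67,3
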