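snp_id,locus,risk_allele,other_allele,discovery_or,gentrain_score
rs6983561,8q24 region 2,C,T,1.31,0.9
rs1859962,17q24,G,A,1.24,0.9
rs13254738,8q24 region 2,C,T,1.21,0.9
rs10090154,8q24 region 1,T,C,1.12,0.9
rs4242382,8q24 region 1,A,G,1.26,0.9
rs1465618,2p21,A,G,1.22,0.9
rs7000448,8q24 region 3,T,C,1.33,0.9
rs10993994,10q11,T,C,1.15,0.9
rs8102476,19q13,C,T,1.37,0.9
rs12500426,12q13,A,G,1.17,0.9
rs1016343,8q24 region 2,T,C,1.14,0.9
rs620861,8q24 region 4,G,A,1.28,0.45
rs12621278,2q31,A,G,1.19,0.9
rs6983267,8q24 region 3,G,A,1.3,0.9
rs7210100,17q21,A,G,1.35,0.9
Bd11934905,8q24 region 2,T,C,1.1,0.9
syn001,synthetic locus 1,A,G,1.38,0.9
syn002,synthetic locus 2,A,G,1.4,0.9
syn003,synthetic locus 3,A,G,1.42,0.9
syn004,synthetic locus 4,C,T,1.44,0.9
syn005,synthetic locus 5,A,G,1.46,0.9
syn006,synthetic locus 6,G,A,1.47,0.9
syn007,synthetic locus 7,G,A,1.49,0.9
syn008,synthetic locus 8,T,C,1.51,0.9
syn009,synthetic locus 9,T,C,1.53,0.9
syn010,synthetic locus 10,T,C,1.54,0.9
syn011,synthetic locus 11,A,G,1.56,0.9
syn012,synthetic locus 12,G,A,1.58,0.9
syn013,synthetic locus 13,T,C,1.6,0.9
syn014,synthetic locus 14,C,T,1.62,0.9
syn015,synthetic locus 15,C,T,1.63,0.9
syn016,synthetic locus 16,T,C,1.65,0.9
syn017,synthetic locus 17,G,A,1.67,0.9
syn018,synthetic locus 18,G,A,1.69,0.9
syn019,synthetic locus 19,A,G,1.7,0.9
syn020,synthetic locus 20,C,T,1.72,0.9
syn021,synthetic locus 21,A,G,1.74,0.9
syn022,synthetic locus 22,T,C,1.76,0.9
syn023,synthetic locus 23,C,T,1.78,0.9
syn024,synthetic locus 24,C,T,1.79,0.9
syn025,synthetic locus 25,C,T,1.81,0.9
syn026,synthetic locus 26,C,T,1.83,0.9
syn027,synthetic locus 27,C,T,1.85,0.9
syn028,synthetic locus 28,A,G,1.86,0.9
syn029,synthetic locus 29,A,G,1.88,0.9
syn030,synthetic locus 30,T,C,1.9,0.9
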