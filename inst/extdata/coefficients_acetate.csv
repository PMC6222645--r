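system,compound,term,value,letter
acetate,alloxydim,b0,98.50,a
acetate,sethoxydim,b0,96.30,a
acetate,profoxydim,b0,99.42,a
acetate,deallyloxylated-alloxydim,b0,96.52,a
acetate,deethoxylated-sethoxydim,b0,96.65,a
acetate,sethoxydim-oxazole,b0,93.59,a
acetate,alloxydim,SW,-2.046,a
acetate,sethoxydim,SW,-1.623,a
acetate,profoxydim,SW,-0.9979,a
acetate,deallyloxylated-alloxydim,SW,-1.397,a
acetate,deethoxylated-sethoxydim,SW,-1.233,a
acetate,sethoxydim-oxazole,SW,-5.374,a
acetate,alloxydim,AM,-4.199,a
acetate,sethoxydim,AM,-6.918,a
acetate,profoxydim,AM,-5.900,a
acetate,deallyloxylated-alloxydim,AM,-0.5917,c
acetate,deethoxylated-sethoxydim,AM,-0.6606,c
acetate,sethoxydim-oxazole,AM,14.45,a
acetate,alloxydim,EV,-0.3586,
acetate,sethoxydim,EV,-0.4540,c
acetate,profoxydim,EV,-0.2489,
acetate,deallyloxylated-alloxydim,EV,-0.3171,
acetate,deethoxylated-sethoxydim,EV,-0.8767,b
acetate,sethoxydim-oxazole,EV,3.544,a
acetate,alloxydim,WC,0.7559,c
acetate,sethoxydim,WC,0.4174,
acetate,profoxydim,WC,0.7932,b
acetate,deallyloxylated-alloxydim,WC,0.7751,b
acetate,deethoxylated-sethoxydim,WC,1.075,a
acetate,sethoxydim-oxazole,WC,2.006,a
acetate,alloxydim,ET,0.2162,
acetate,sethoxydim,ET,0.3104,
acetate,profoxydim,ET,-0.04629,
acetate,deallyloxylated-alloxydim,ET,0.7781,b
acetate,deethoxylated-sethoxydim,ET,0.5730,d
acetate,sethoxydim-oxazole,ET,0.6799,c
acetate,alloxydim,SW:AM,-1.001,c
acetate,sethoxydim,SW:AM,0.006950,
acetate,profoxydim,SW:AM,1.500,a
acetate,deallyloxylated-alloxydim,SW:AM,0.4094,
acetate,deethoxylated-sethoxydim,SW:AM,0.1525,
acetate,sethoxydim-oxazole,SW:AM,2.818,a
acetate,alloxydim,SW:EV,-0.7845,c
acetate,sethoxydim,SW:EV,-1.148,a
acetate,profoxydim,SW:EV,0.2673,
acetate,deallyloxylated-alloxydim,SW:EV,-0.6982,c
acetate,deethoxylated-sethoxydim,SW:EV,-0.6762,c
acetate,sethoxydim-oxazole,SW:EV,-0.4862,d
acetate,alloxydim,SW:WC,1.452,a
acetate,sethoxydim,SW:WC,1.084,a
acetate,profoxydim,SW:WC,1.852,a
acetate,deallyloxylated-alloxydim,SW:WC,1.181,a
acetate,deethoxylated-sethoxydim,SW:WC,0.9806,a
acetate,sethoxydim-oxazole,SW:WC,1.086,a
acetate,alloxydim,SW:ET,0.1732,
acetate,sethoxydim,SW:ET,-0.08985,
acetate,profoxydim,SW:ET,0.1410,
acetate,deallyloxylated-alloxydim,SW:ET,-0.03353,
acetate,deethoxylated-sethoxydim,SW:ET,-0.05905,
acetate,sethoxydim-oxazole,SW:ET,-0.05778,
acetate,alloxydim,AM:EV,-0.5958,
acetate,sethoxydim,AM:EV,-0.7734,b
acetate,profoxydim,AM:EV,-0.5355,c
acetate,deallyloxylated-alloxydim,AM:EV,-1.098,a
acetate,deethoxylated-sethoxydim,AM:EV,-1.141,a
acetate,sethoxydim-oxazole,AM:EV,-5.220,a
acetate,alloxydim,AM:WC,-0.8033,c
acetate,sethoxydim,AM:WC,-0.7921,b
acetate,profoxydim,AM:WC,0.3970,
acetate,deallyloxylated-alloxydim,AM:WC,-0.5502,
acetate,deethoxylated-sethoxydim,AM:WC,-0.4931,
acetate,sethoxydim-oxazole,AM:WC,-1.827,a
acetate,alloxydim,AM:ET,-1.327,a
acetate,sethoxydim,AM:ET,-1.159,a
acetate,profoxydim,AM:ET,-0.8263,a
acetate,deallyloxylated-alloxydim,AM:ET,-0.9402,b
acetate,deethoxylated-sethoxydim,AM:ET,-1.046,a
acetate,sethoxydim-oxazole,AM:ET,-1.023,a
acetate,alloxydim,EV:WC,0.7362,d
acetate,sethoxydim,EV:WC,0.8608,c
acetate,profoxydim,EV:WC,0.6544,c
acetate,deallyloxylated-alloxydim,EV:WC,0.5351,d
acetate,deethoxylated-sethoxydim,EV:WC,0.6066,c
acetate,sethoxydim-oxazole,EV:WC,-0.08351,
acetate,alloxydim,EV:ET,0.3184,
acetate,sethoxydim,EV:ET,-0.1492,
acetate,profoxydim,EV:ET,-0.2950,
acetate,deallyloxylated-alloxydim,EV:ET,0.09183,
acetate,deethoxylated-sethoxydim,EV:ET,-0.1445,
acetate,sethoxydim-oxazole,EV:ET,-0.2852,
acetate,alloxydim,WC:ET,0.2434,
acetate,sethoxydim,WC:ET,-0.06107,
acetate,profoxydim,WC:ET,-0.1582,
acetate,deallyloxylated-alloxydim,WC:ET,0.07877,
acetate,deethoxylated-sethoxydim,WC:ET,0.1107,
acetate,sethoxydim-oxazole,WC:ET,0.7931,b
acetate,alloxydim,SW:AM:EV,-0.08380,
acetate,sethoxydim,SW:AM:EV,-0.6281,c
acetate,profoxydim,SW:AM:EV,-1.232,a
acetate,deallyloxylated-alloxydim,SW:AM:EV,-0.2973,
acetate,deethoxylated-sethoxydim,SW:AM:EV,-0.6082,c
acetate,sethoxydim-oxazole,SW:AM:EV,-0.7774,b
acetate,alloxydim,SW:AM:WC,-0.4183,
acetate,sethoxydim,SW:AM:WC,-0.8071,b
acetate,profoxydim,SW:AM:WC,-1.498,a
acetate,deallyloxylated-alloxydim,SW:AM:WC,-0.6732,c
acetate,deethoxylated-sethoxydim,SW:AM:WC,-0.8846,b
acetate,sethoxydim-oxazole,SW:AM:WC,-0.8068,b
acetate,alloxydim,SW:AM:ET,0.2012,
acetate,sethoxydim,SW:AM:ET,-0.04719,
acetate,profoxydim,SW:AM:ET,-0.4896,d
acetate,deallyloxylated-alloxydim,SW:AM:ET,-0.08773,
acetate,deethoxylated-sethoxydim,SW:AM:ET,-0.1503,
acetate,sethoxydim-oxazole,SW:AM:ET,-0.5721,c
acetate,alloxydim,SW:EV:WC,-0.2389,
acetate,sethoxydim,SW:EV:WC,0.1304,d
acetate,profoxydim,SW:EV:WC,0.6455,c
acetate,deallyloxylated-alloxydim,SW:EV:WC,0.07467,d
acetate,deethoxylated-sethoxydim,SW:EV:WC,0.02193,d
acetate,sethoxydim-oxazole,SW:EV:WC,0.4043,
acetate,alloxydim,SW:EV:ET,0.1344,
acetate,sethoxydim,SW:EV:ET,0.5538,
acetate,profoxydim,SW:EV:ET,0.4635,
acetate,deallyloxylated-alloxydim,SW:EV:ET,0.8739,b
acetate,deethoxylated-sethoxydim,SW:EV:ET,0.5816,
acetate,sethoxydim-oxazole,SW:EV:ET,0.02332,
acetate,alloxydim,SW:WC:ET,0.2797,
acetate,sethoxydim,SW:WC:ET,0.5672,d
acetate,profoxydim,SW:WC:ET,0.7497,b
acetate,deallyloxylated-alloxydim,SW:WC:ET,0.2862,
acetate,deethoxylated-sethoxydim,SW:WC:ET,0.5585,d
acetate,sethoxydim-oxazole,SW:WC:ET,-0.1483,
acetate,alloxydim,AM:EV:WC,0.05389,
acetate,sethoxydim,AM:EV:WC,-0.2829,
acetate,profoxydim,AM:EV:WC,-0.4543,d
acetate,deallyloxylated-alloxydim,AM:EV:WC,-0.5252,d
acetate,deethoxylated-sethoxydim,AM:EV:WC,-0.5960,c
acetate,sethoxydim-oxazole,AM:EV:WC,0.2494,
acetate,alloxydim,AM:EV:ET,0.2714,
acetate,sethoxydim,AM:EV:ET,0.04895,
acetate,profoxydim,AM:EV:ET,0.1469,
acetate,deallyloxylated-alloxydim,AM:EV:ET,-0.1186,
acetate,deethoxylated-sethoxydim,AM:EV:ET,-0.3965,
acetate,sethoxydim-oxazole,AM:EV:ET,-0.1905,
acetate,alloxydim,AM:WC:ET,0.2759,
acetate,sethoxydim,AM:WC:ET,-0.1020,
acetate,profoxydim,AM:WC:ET,0.1953,
acetate,deallyloxylated-alloxydim,AM:WC:ET,0.09603,
acetate,deethoxylated-sethoxydim,AM:WC:ET,0.2365,
acetate,sethoxydim-oxazole,AM:WC:ET,-0.2606,
acetate,alloxydim,EV:WC:ET,-0.3355,
acetate,sethoxydim,EV:WC:ET,-0.07306,
acetate,profoxydim,EV:WC:ET,0.1628,
acetate,deallyloxylated-alloxydim,EV:WC:ET,-0.1769,
acetate,deethoxylated-sethoxydim,EV:WC:ET,-0.08688,
acetate,sethoxydim-oxazole,EV:WC:ET,0.2886,
acetate,alloxydim,SW^2,0.1189,
acetate,sethoxydim,SW^2,-0.1245,
acetate,profoxydim,SW^2,1.538,d
acetate,deallyloxylated-alloxydim,SW^2,-1.291,
acetate,deethoxylated-sethoxydim,SW^2,-1.249,
acetate,sethoxydim-oxazole,SW^2,-0.7618,
acetate,alloxydim,AM^2,-7.183,a
acetate,sethoxydim,AM^2,-8.683,a
acetate,profoxydim,AM^2,-7.731,a
acetate,deallyloxylated-alloxydim,AM^2,-3.467,a
acetate,deethoxylated-sethoxydim,AM^2,-3.124,b
acetate,sethoxydim-oxazole,AM^2,-12.42,a
acetate,alloxydim,EV^2,3.876,b
acetate,sethoxydim,EV^2,3.331,a
acetate,profoxydim,EV^2,0.7742,
acetate,deallyloxylated-alloxydim,EV^2,2.272,c
acetate,deethoxylated-sethoxydim,EV^2,2.575,c
acetate,sethoxydim-oxazole,EV^2,1.251,
acetate,alloxydim,WC^2,-1.693,
acetate,sethoxydim,WC^2,-0.7284,
acetate,profoxydim,WC^2,-0.1338,
acetate,deallyloxylated-alloxydim,WC^2,-0.5212,
acetate,deethoxylated-sethoxydim,WC^2,-0.9923,
acetate,sethoxydim-oxazole,WC^2,-0.3232,
acetate,alloxydim,ET^2,1.262,
acetate,sethoxydim,ET^2,1.740,d
acetate,profoxydim,ET^2,1.222,
acetate,deallyloxylated-alloxydim,ET^2,2.566,c
acetate,deethoxylated-sethoxydim,ET^2,1.767,d
acetate,sethoxydim-oxazole,ET^2,1.881,d
acetate,alloxydim,R,0.9458,
acetate,sethoxydim,R,0.9829,
acetate,profoxydim,R,0.9830,
acetate,deallyloxylated-alloxydim,R,0.9002,
acetate,deethoxylated-sethoxydim,R,0.9085,
acetate,sethoxydim-oxazole,R,0.9964,
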