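system,compound,term,value,letter
citrate,alloxydim,b0,101.6,a
citrate,sethoxydim,b0,106.9,a
citrate,profoxydim,b0,105.8,a
citrate,deallyloxylated-alloxydim,b0,100.3,a
citrate,deethoxylated-sethoxydim,b0,103.0,a
citrate,sethoxydim-oxazole,b0,103.7,a
citrate,alloxydim,SW,-0.8269,
citrate,sethoxydim,SW,1.751,
citrate,profoxydim,SW,-2.371,a
citrate,deallyloxylated-alloxydim,SW,-0.5147,
citrate,deethoxylated-sethoxydim,SW,0.3115,
citrate,sethoxydim-oxazole,SW,-1.607,c
citrate,alloxydim,AM,-4.959,a
citrate,sethoxydim,AM,-4.854,a
citrate,profoxydim,AM,-6.367,a
citrate,deallyloxylated-alloxydim,AM,-2.014,a
citrate,deethoxylated-sethoxydim,AM,-2.067,a
citrate,sethoxydim-oxazole,AM,10.12,a
citrate,alloxydim,EV,0.8366,
citrate,sethoxydim,EV,1.933,c
citrate,profoxydim,EV,3.194,a
citrate,deallyloxylated-alloxydim,EV,0.9733,d
citrate,deethoxylated-sethoxydim,EV,1.417,c
citrate,sethoxydim-oxazole,EV,4.717,a
citrate,alloxydim,WC,-0.6412,
citrate,sethoxydim,WC,-0.3913,
citrate,profoxydim,WC,-1.231,c
citrate,deallyloxylated-alloxydim,WC,0.5237,
citrate,deethoxylated-sethoxydim,WC,0.5356,
citrate,sethoxydim-oxazole,WC,1.105,
citrate,alloxydim,ET,0.9447,d
citrate,sethoxydim,ET,0.3545,
citrate,profoxydim,ET,0.8743,
citrate,deallyloxylated-alloxydim,ET,1.373,c
citrate,deethoxylated-sethoxydim,ET,1.370,c
citrate,sethoxydim-oxazole,ET,0.3711,
citrate,alloxydim,SW:AM,-0.02532,
citrate,sethoxydim,SW:AM,0.2443,
citrate,profoxydim,SW:AM,-0.3971,
citrate,deallyloxylated-alloxydim,SW:AM,0.6546,
citrate,deethoxylated-sethoxydim,SW:AM,0.5940,
citrate,sethoxydim-oxazole,SW:AM,3.398,a
citrate,alloxydim,SW:EV,0.6864,d
citrate,sethoxydim,SW:EV,2.109,c
citrate,profoxydim,SW:EV,-0.5446,
citrate,deallyloxylated-alloxydim,SW:EV,1.497,c
citrate,deethoxylated-sethoxydim,SW:EV,1.537,c
citrate,sethoxydim-oxazole,SW:EV,2.265,b
citrate,alloxydim,SW:WC,-1.263,c
citrate,sethoxydim,SW:WC,0.006918,
citrate,profoxydim,SW:WC,-0.6714,
citrate,deallyloxylated-alloxydim,SW:WC,-0.9634,
citrate,deethoxylated-sethoxydim,SW:WC,-0.7483,
citrate,sethoxydim-oxazole,SW:WC,0.03950,
citrate,alloxydim,SW:ET,1.381,c
citrate,sethoxydim,SW:ET,0.8230,
citrate,profoxydim,SW:ET,2.471,a
citrate,deallyloxylated-alloxydim,SW:ET,1.489,c
citrate,deethoxylated-sethoxydim,SW:ET,1.656,c
citrate,sethoxydim-oxazole,SW:ET,0.8718,
citrate,alloxydim,AM:EV,-1.804,b
citrate,sethoxydim,AM:EV,-1.713,d
citrate,profoxydim,AM:EV,-2.164,a
citrate,deallyloxylated-alloxydim,AM:EV,-1.146,d
citrate,deethoxylated-sethoxydim,AM:EV,-1.162,d
citrate,sethoxydim-oxazole,AM:EV,-4.017,a
citrate,alloxydim,AM:WC,1.396,c
citrate,sethoxydim,AM:WC,1.685,d
citrate,profoxydim,AM:WC,2.381,a
citrate,deallyloxylated-alloxydim,AM:WC,1.710,b
citrate,deethoxylated-sethoxydim,AM:WC,1.882,b
citrate,sethoxydim-oxazole,AM:WC,0.8537,
citrate,alloxydim,AM:ET,-0.6283,
citrate,sethoxydim,AM:ET,-0.6910,
citrate,profoxydim,AM:ET,-0.8073,
citrate,deallyloxylated-alloxydim,AM:ET,-0.4672,
citrate,deethoxylated-sethoxydim,AM:ET,-0.3677,
citrate,sethoxydim-oxazole,AM:ET,0.3240,
citrate,alloxydim,EV:WC,0.06119,
citrate,sethoxydim,EV:WC,1.099,
citrate,profoxydim,EV:WC,-0.4256,
citrate,deallyloxylated-alloxydim,EV:WC,-0.6932,
citrate,deethoxylated-sethoxydim,EV:WC,-0.7470,
citrate,sethoxydim-oxazole,EV:WC,-0.9536,
citrate,alloxydim,EV:ET,-0.8625,
citrate,sethoxydim,EV:ET,-1.158,
citrate,profoxydim,EV:ET,-0.7665,
citrate,deallyloxylated-alloxydim,EV:ET,-1.217,c
citrate,deethoxylated-sethoxydim,EV:ET,-1.651,c
citrate,sethoxydim-oxazole,EV:ET,-1.030,
citrate,alloxydim,WC:ET,0.3770,
citrate,sethoxydim,WC:ET,0.7965,
citrate,profoxydim,WC:ET,0.02497,
citrate,deallyloxylated-alloxydim,WC:ET,0.6367,
citrate,deethoxylated-sethoxydim,WC:ET,0.7979,
citrate,sethoxydim-oxazole,WC:ET,1.111,
citrate,alloxydim,SW:AM:EV,-0.5365,
citrate,sethoxydim,SW:AM:EV,-0.5793,
citrate,profoxydim,SW:AM:EV,-0.7477,
citrate,deallyloxylated-alloxydim,SW:AM:EV,-0.2786,
citrate,deethoxylated-sethoxydim,SW:AM:EV,0.001259,
citrate,sethoxydim-oxazole,SW:AM:EV,-0.5633,
citrate,alloxydim,SW:AM:WC,0.1645,
citrate,sethoxydim,SW:AM:WC,-0.09995,
citrate,profoxydim,SW:AM:WC,1.413,c
citrate,deallyloxylated-alloxydim,SW:AM:WC,0.7606,
citrate,deethoxylated-sethoxydim,SW:AM:WC,1.248,d
citrate,sethoxydim-oxazole,SW:AM:WC,1.142,
citrate,alloxydim,SW:AM:ET,-0.6347,
citrate,sethoxydim,SW:AM:ET,-0.6291,
citrate,profoxydim,SW:AM:ET,-0.6368,
citrate,deallyloxylated-alloxydim,SW:AM:ET,-0.5067,
citrate,deethoxylated-sethoxydim,SW:AM:ET,-0.4016,c
citrate,sethoxydim-oxazole,SW:AM:ET,-0.2854,
citrate,alloxydim,SW:EV:WC,0.6929,
citrate,sethoxydim,SW:EV:WC,1.650,d
citrate,profoxydim,SW:EV:WC,0.2431,
citrate,deallyloxylated-alloxydim,SW:EV:WC,0.2161,
citrate,deethoxylated-sethoxydim,SW:EV:WC,0.1957,
citrate,sethoxydim-oxazole,SW:EV:WC,0.4587,
citrate,alloxydim,SW:EV:ET,-0.8404,
citrate,sethoxydim,SW:EV:ET,-1.135,
citrate,profoxydim,SW:EV:ET,-0.04247,
citrate,deallyloxylated-alloxydim,SW:EV:ET,-1.062,d
citrate,deethoxylated-sethoxydim,SW:EV:ET,-1.513,d
citrate,sethoxydim-oxazole,SW:EV:ET,-0.6957,
citrate,alloxydim,SW:WC:ET,-0.2049,
citrate,sethoxydim,SW:WC:ET,0.1874,
citrate,profoxydim,SW:WC:ET,-0.6880,
citrate,deallyloxylated-alloxydim,SW:WC:ET,-0.2849,
citrate,deethoxylated-sethoxydim,SW:WC:ET,-0.2937,
citrate,sethoxydim-oxazole,SW:WC:ET,0.1272,
citrate,alloxydim,AM:EV:WC,-1.505,c
citrate,sethoxydim,AM:EV:WC,-2.514,b
citrate,profoxydim,AM:EV:WC,-2.980,a
citrate,deallyloxylated-alloxydim,AM:EV:WC,-1.443,c
citrate,deethoxylated-sethoxydim,AM:EV:WC,-2.404,a
citrate,sethoxydim-oxazole,AM:EV:WC,-2.534,a
citrate,alloxydim,AM:EV:ET,0.09265,
citrate,sethoxydim,AM:EV:ET,-0.5385,
citrate,profoxydim,AM:EV:ET,0.03543,
citrate,deallyloxylated-alloxydim,AM:EV:ET,-0.09737,
citrate,deethoxylated-sethoxydim,AM:EV:ET,-0.5561,
citrate,sethoxydim-oxazole,AM:EV:ET,-0.6266,
citrate,alloxydim,AM:WC:ET,-0.6797,
citrate,sethoxydim,AM:WC:ET,-0.3485,
citrate,profoxydim,AM:WC:ET,-0.5506,
citrate,deallyloxylated-alloxydim,AM:WC:ET,-0.6236,
citrate,deethoxylated-sethoxydim,AM:WC:ET,-0.6813,
citrate,sethoxydim-oxazole,AM:WC:ET,-0.2181,
citrate,alloxydim,EV:WC:ET,-0.3661,
citrate,sethoxydim,EV:WC:ET,-0.3285,
citrate,profoxydim,EV:WC:ET,-0.1668,
citrate,deallyloxylated-alloxydim,EV:WC:ET,-0.5718,
citrate,deethoxylated-sethoxydim,EV:WC:ET,-0.7661,
citrate,sethoxydim-oxazole,EV:WC:ET,-0.3618,
citrate,alloxydim,SW^2,-0.05830,
citrate,sethoxydim,SW^2,-6.134,d
citrate,profoxydim,SW^2,5.027,c
citrate,deallyloxylated-alloxydim,SW^2,-0.6877,
citrate,deethoxylated-sethoxydim,SW^2,-1.293,
citrate,sethoxydim-oxazole,SW^2,-2.781,
citrate,alloxydim,AM^2,-4.073,d
citrate,sethoxydim,AM^2,-3.410,
citrate,profoxydim,AM^2,-5.206,c
citrate,deallyloxylated-alloxydim,AM^2,-2.465,
citrate,deethoxylated-sethoxydim,AM^2,-2.349,
citrate,sethoxydim-oxazole,AM^2,-10.91,a
citrate,alloxydim,EV^2,-1.734,
citrate,sethoxydim,EV^2,-2.347,
citrate,profoxydim,EV^2,-3.375,
citrate,deallyloxylated-alloxydim,EV^2,-1.115,
citrate,deethoxylated-sethoxydim,EV^2,-2.028,
citrate,sethoxydim-oxazole,EV^2,-1.976,
citrate,alloxydim,WC^2,-2.133,
citrate,sethoxydim,WC^2,-1.699,
citrate,profoxydim,WC^2,-3.023,
citrate,deallyloxylated-alloxydim,WC^2,-1.159,
citrate,deethoxylated-sethoxydim,WC^2,-1.306,
citrate,sethoxydim-oxazole,WC^2,-0.9245,
citrate,alloxydim,ET^2,-0.1019,
citrate,sethoxydim,ET^2,-0.2822,
citrate,profoxydim,ET^2,-0.8741,
citrate,deallyloxylated-alloxydim,ET^2,-0.9409,
citrate,deethoxylated-sethoxydim,ET^2,-0.5995,
citrate,sethoxydim-oxazole,ET^2,-1.470,
citrate,alloxydim,R,0.9228,
citrate,sethoxydim,R,0.8905,
citrate,profoxydim,R,0.9520,
citrate,deallyloxylated-alloxydim,R,0.8761,
citrate,deethoxylated-sethoxydim,R,0.8837,
citrate,sethoxydim-oxazole,R,0.9674,
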