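system,SW,AM,EV,WC,ET
citrate,3.23,52.8,8,3.8,1.8
acetate,3.96,57.0,9.4,4.0,2.8
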