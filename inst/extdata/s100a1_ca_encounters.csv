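residue,subunit,fet_ps,set_ps,trt_ps
D24,A,7948,0,72057
E32,A,0,0,0
K27,A,58594,77385,22856
D62,A,0,0,0
D66,A,11028,0,68975
E68,A,280,0,79720
E73,A,588,0,79412
S29,A,3202,11046,5394
N64,A,10046,0,1980
S19,A,0,0,0
E63,A,11699,41928,15686
D24,B,9411,0,33566
E32,B,0,0,0
K27,B,0,0,0
D62,B,588,0,19118
D66,B,20135,0,59865
E68,B,22750,0,40004
E73,B,28882,0,51118
S29,B,21156,25750,1548
N64,B,0,0,0
S19,B,0,0,0
E63,B,1078,0,18138
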