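specimen,stage,nNormal,nAbnormal
H-1,H,271,660
H-2,H,481,1088
H-3,H,244,529
H-4,H,117,385
H-5,H,289,1098
H-6,H,721,1653
H-7,H,292,655
H-8,H,165,817
H-9,H,446,1013
H-10,H,59,151
M-1,M,382,687
M-2,M,318,591
M-3,M,192,360
M-4,M,131,187
M-5,M,308,652
M-6,M,173,343
M-7,M,335,456
M-8,M,726,1311
M-9,M,382,647
M-10,M,379,795
L-1,L,824,771
L-2,L,1080,1210
L-3,L,520,636
L-4,L,404,477
L-5,L,862,1165
L-6,L,123,259
N-1,N,473,247
N-2,N,310,205
N-3,N,292,308
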