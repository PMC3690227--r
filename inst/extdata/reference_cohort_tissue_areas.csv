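specimen,stage,areaNormal,areaAbnormal
H-1,H,31791895,12495997
H-2,H,30894213,10986876
H-3,H,31869804,11038359
H-4,H,32511973,11026116
H-5,H,33797170,10267132
H-6,H,31635397,11474053
H-7,H,31451368,11224479
H-8,H,32950410,11695269
H-9,H,34067450,10887277
H-10,H,27747278,10290969
M-1,M,35698059,7946874
M-2,M,34326147,8515580
M-3,M,35324719,8461582
M-4,M,33284256,7671304
M-5,M,34422738,9418395
M-6,M,34315916,9170559
M-7,M,33027627,9072248
M-8,M,34051300,7529957
M-9,M,35167293,8706583
M-10,M,32745438,8083811
L-1,L,40491940,5972857
L-2,L,43877544,2773360
L-3,L,36923582,6077911
L-4,L,37539086,4417329
L-5,L,34975123,7460192
L-6,L,36623101,5244448
N-1,N,40904631,5482052
N-2,N,32792539,3323970
N-3,N,32724101,4340358
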