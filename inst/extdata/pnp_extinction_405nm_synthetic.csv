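"ph","epsilon"
6,1190
6.25,2013
6.5,3293
6.75,5125
7,7461
7.25,10032
7.5,12442
7.75,14386
8,15772
8.25,16675
8.5,17230
8.75,17559
9,17749
9.25,17858
9.5,17920
9.75,17955
10,17975
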