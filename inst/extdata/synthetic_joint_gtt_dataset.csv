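"series_id","observable","culture_type","regime","gtt","time_h","mean","sem","n"
"co-culture:hyper:d1:glucose","glucose","co-culture","hyper","d1",0,11.4854343153418,0.340864737319972,5
"co-culture:hyper:d1:glucose","glucose","co-culture","hyper","d1",8,10.5992257019002,0.458581293048295,5
"co-culture:hyper:d1:insulin","insulin","co-culture","hyper","d1",8,352.105388453181,21.9179178389482,5
"co-culture:hyper:d1:glucose","glucose","co-culture","hyper","d1",24,6.87843070338324,0.592913361775578,5
"co-culture:hyper:d1:insulin","insulin","co-culture","hyper","d1",24,479.996298866547,30.2566069562436,5
"co-culture:hyper:d1:glucose","glucose","co-culture","hyper","d1",48,4.48902898476392,0.170754518816414,5
"co-culture:hyper:d1:insulin","insulin","co-culture","hyper","d1",48,321.499115904602,8.52581665619166,5
"co-culture:hyper:d13:glucose","glucose","co-culture","hyper","d13",0,9.73929872856958,0.463412570618905,5
"co-culture:hyper:d13:glucose","glucose","co-culture","hyper","d13",8,9.88003391299593,0.374371491938875,5
"co-culture:hyper:d13:insulin","insulin","co-culture","hyper","d13",8,139.049741397324,5.4343644031498,5
"co-culture:hyper:d13:glucose","glucose","co-culture","hyper","d13",24,8.77552979020713,0.324500437043504,5
"co-culture:hyper:d13:insulin","insulin","co-culture","hyper","d13",24,188.072946349011,13.0740963869756,5
"co-culture:hyper:d13:glucose","glucose","co-culture","hyper","d13",48,6.45084207697777,0.234859986966349,5
"co-culture:hyper:d13:insulin","insulin","co-culture","hyper","d13",48,162.421559547415,2.42327859821595,5
"co-culture:normo:d13:glucose","glucose","co-culture","normo","d13",0,10.5586493461845,0.337608307004776,5
"co-culture:normo:d13:glucose","glucose","co-culture","normo","d13",8,10.1035512132089,0.401139254721675,5
"co-culture:normo:d13:insulin","insulin","co-culture","normo","d13",8,111.631311848521,4.77826672092951,5
"co-culture:normo:d13:glucose","glucose","co-culture","normo","d13",24,8.59742655661305,0.204933433492197,5
"co-culture:normo:d13:insulin","insulin","co-culture","normo","d13",24,161.265316723931,7.83397093839625,5
"co-culture:normo:d13:glucose","glucose","co-culture","normo","d13",48,5.71638209702946,0.238226833227423,5
"co-culture:normo:d13:insulin","insulin","co-culture","normo","d13",48,120.032207069019,6.38760240122615,5
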