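"mother_id","year","offspring","exposure"
"f1",2010,5,1
"f2",2010,3,1
"f3",2010,1,1
"f4",2010,0,1
"f5",2010,4,1
"f6",2010,2,1
"f7",2010,1,1
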