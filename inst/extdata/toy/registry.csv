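"individual_id","year","sex","age_class","colony","n_traps"
"f1",2010,"F","adult","picnic",8
"f2",2010,"F","adult","picnic",9
"f3",2010,"F","adult","picnic",7
"f4",2010,"F","adult","picnic",11
"f5",2010,"F","adult","picnic",6
"f6",2010,"F","adult","picnic",8
"f7",2010,"F","adult","picnic",10
"m1",2010,"M","adult","picnic",7
"f8",2010,"F","yearling","picnic",6
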