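"individual_id","date","location"
"f1","2010-05-03","burrow_A"
"f1","2010-05-08","burrow_A"
"f1","2010-05-11","burrow_A"
"f1","2010-05-14","burrow_A"
"f1","2010-05-15","burrow_A"
"f1","2010-05-18","burrow_A"
"f1","2010-05-19","burrow_A"
"f2","2010-05-02","burrow_A"
"f2","2010-05-05","burrow_A"
"f2","2010-05-07","burrow_A"
"f2","2010-05-09","burrow_A"
"f2","2010-05-13","burrow_A"
"f2","2010-05-15","burrow_A"
"f2","2010-05-17","burrow_A"
"f2","2010-05-18","burrow_A"
"f3","2010-05-01","burrow_A"
"f3","2010-05-02","burrow_A"
"f3","2010-05-03","burrow_A"
"f3","2010-05-05","burrow_A"
"f3","2010-05-11","burrow_A"
"f3","2010-05-12","burrow_A"
"f3","2010-05-13","burrow_A"
"f3","2010-05-15","burrow_A"
"f3","2010-05-18","burrow_A"
"f3","2010-05-19","burrow_A"
"f4","2010-05-06","burrow_A"
"f4","2010-05-07","burrow_A"
"f4","2010-05-10","burrow_A"
"f4","2010-05-11","burrow_A"
"f4","2010-05-12","burrow_A"
"f4","2010-05-13","burrow_A"
"f4","2010-05-14","burrow_A"
"f4","2010-05-15","burrow_A"
"f4","2010-05-17","burrow_A"
"f4","2010-05-18","burrow_A"
"f4","2010-05-20","burrow_A"
"f5","2010-05-02","burrow_B"
"f5","2010-05-03","burrow_B"
"f5","2010-05-07","burrow_B"
"f5","2010-05-08","burrow_B"
"f5","2010-05-09","burrow_B"
"f5","2010-05-10","burrow_B"
"f5","2010-05-12","burrow_B"
"f5","2010-05-13","burrow_B"
"f5","2010-05-17","burrow_B"
"f6","2010-05-02","burrow_B"
"f6","2010-05-03","burrow_B"
"f6","2010-05-04","burrow_B"
"f6","2010-05-10","burrow_B"
"f6","2010-05-14","burrow_B"
"f6","2010-05-17","burrow_B"
"f6","2010-05-18","burrow_B"
"f7","2010-05-01","burrow_B"
"f7","2010-05-02","burrow_B"
"f7","2010-05-06","burrow_B"
"f7","2010-05-09","burrow_B"
"f7","2010-05-18","burrow_B"
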