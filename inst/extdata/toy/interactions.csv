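"timestamp","initiator_id","recipient_id","itype","location"
"2010-05-03 08:00:00","f1","f2","agonistic","burrow_A"
"2010-05-04 08:00:00","f1","f3","agonistic","burrow_A"
"2010-05-05 08:00:00","f1","f4","agonistic","burrow_A"
"2010-05-06 08:00:00","f2","f3","agonistic","burrow_A"
"2010-05-07 08:00:00","f2","f4","agonistic","burrow_A"
"2010-05-08 08:00:00","f3","f4","agonistic","burrow_A"
"2010-05-09 08:00:00","f1","f2","agonistic","burrow_A"
"2010-05-10 08:00:00","f2","f1","agonistic","burrow_A"
"2010-05-11 08:00:00","f5","f6","agonistic","burrow_B"
"2010-05-12 08:00:00","f5","f7","agonistic","burrow_B"
"2010-05-13 08:00:00","f6","f7","agonistic","burrow_B"
"2010-05-14 08:00:00","f7","f6","agonistic","burrow_B"
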