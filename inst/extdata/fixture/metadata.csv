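"sample_id","organ","processing","replicate","is_blank"
"r_e_1","root","extract",1,FALSE
"r_e_2","root","extract",2,FALSE
"r_e_3","root","extract",3,FALSE
"s_e_1","seed","extract",1,FALSE
"s_e_2","seed","extract",2,FALSE
"s_e_3","seed","extract",3,FALSE
"r_j_1","root","juice",1,FALSE
"r_j_2","root","juice",2,FALSE
"r_j_3","root","juice",3,FALSE
"s_j_1","seed","juice",1,FALSE
"s_j_2","seed","juice",2,FALSE
"s_j_3","seed","juice",3,FALSE
"blank_1","none","none",1,TRUE
"blank_2","none","none",2,TRUE
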