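display_name,precursor,start,end,pyroglu,disulfides
Abeta1-37,Abeta,1,37,FALSE,0
Abeta1-40,Abeta,1,40,FALSE,0
Abeta2-40,Abeta,2,40,FALSE,0
Abeta3-40,Abeta,3,40,FALSE,0
Abeta3pE-40,Abeta,3,40,TRUE,0
Abeta4-40,Abeta,4,40,FALSE,0
Abeta5-40,Abeta,5,40,FALSE,0
Abeta8-40,Abeta,8,40,FALSE,0
Abeta9-40,Abeta,9,40,FALSE,0
Abeta11-40,Abeta,11,40,FALSE,0
Abeta11pE-40,Abeta,11,40,TRUE,0
Abeta1-42,Abeta,1,42,FALSE,0
Abeta3pE-42,Abeta,3,42,TRUE,0
Abeta4-42,Abeta,4,42,FALSE,0
Abeta11pE-42,Abeta,11,42,TRUE,0
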