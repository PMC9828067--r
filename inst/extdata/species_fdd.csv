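display_name,precursor,start,end,pyroglu,disulfides
ADan1-34,ADan,1,34,FALSE,1
ADan1pE-34,ADan,1,34,TRUE,1
ADan3-34,ADan,3,34,FALSE,1
ADan1-33,ADan,1,33,FALSE,1
ADan1pE-33,ADan,1,33,TRUE,1
ADan3-33,ADan,3,33,FALSE,1
ADan1-29,ADan,1,29,FALSE,1
ADan1pE-29,ADan,1,29,TRUE,1
ADan1-28,ADan,1,28,FALSE,1
ADan1pE-28,ADan,1,28,TRUE,1
Abeta1-40,Abeta,1,40,FALSE,0
Abeta3-40,Abeta,3,40,FALSE,0
Abeta3pE-40,Abeta,3,40,TRUE,0
Abeta1-42,Abeta,1,42,FALSE,0
Abeta3-42,Abeta,3,42,FALSE,0
Abeta3pE-42,Abeta,3,42,TRUE,0
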