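display_name,precursor,start,end,pyroglu,disulfides
ABri1-34,ABri,1,34,FALSE,1
ABri1pE-34,ABri,1,34,TRUE,1
ABri2-34,ABri,2,34,FALSE,1
ABri3-34,ABri,3,34,FALSE,1
ABri1-29,ABri,1,29,FALSE,1
ABri1pE-29,ABri,1,29,TRUE,1
ABri2-29,ABri,2,29,FALSE,1
ABri3-29,ABri,3,29,FALSE,1
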