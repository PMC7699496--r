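test,tp,fn,fp,tn
A,52,1,4,3
B,53,0,6,1
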