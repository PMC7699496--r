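test,tp,fn,fp,tn
A,59,16,4,161
B,60,15,4,161
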