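,missing,smoker,ex_smoker,never_smoker
missing,5,100,124,203
smoker,10,985,194,20
ex_smoker,25,133,1323,143
never_smoker,32,83,540,2916
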