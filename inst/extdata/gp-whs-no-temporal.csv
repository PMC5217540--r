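,missing,smoker,ex_smoker,never_smoker
missing,5,99,120,199
smoker,16,1017,452,236
ex_smoker,22,112,1108,126
never_smoker,29,73,501,2721
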