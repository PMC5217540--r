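,missing,smoker,ex_smoker,never_smoker
missing,5,89,120,199
smoker,17,1040,426,209
ex_smoker,34,130,1449,1104
never_smoker,16,42,186,1770
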