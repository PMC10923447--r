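variable	hi	lo	average
group_n	320	395	443
female	197	250	219
atopy	174	204	313
eosinophilic	122	172	203
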