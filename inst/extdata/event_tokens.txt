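covid
covid19
coronavirus
corona
virus
pandemic
epidemic
outbreak
quarantin*
lockdown*
infect*
vaccin*
ventilator*
sanitizer
distancing
ppe
curfew
contagio*
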