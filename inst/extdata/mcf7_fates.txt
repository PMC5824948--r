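# Fate logic for the synthetic MCF-7 p53 network (first matching rule wins).
FATE apoptosis: CASP
FATE senescence: P21 OR SFN OR RB
FATE proliferation: CYCE
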