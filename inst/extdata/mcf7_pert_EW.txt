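# MCF-7 treatment arm EW
BASAL ATM 1
BASAL WIP1 -1000
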