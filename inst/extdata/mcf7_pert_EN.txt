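# MCF-7 treatment arm EN
BASAL ATM 1
DELETE_EDGE MDM2 P53
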