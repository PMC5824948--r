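# CRC driver arm HCT116
FIX RAS 1
FIX PI3K 1
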