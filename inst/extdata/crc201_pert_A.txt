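# CRC driver arm A
FIX APC 0
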