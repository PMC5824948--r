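# CRC driver arm AKPT
FIX APC 0
FIX KRAS 1
FIX PTEN 0
FIX TP53 0
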