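# Fate logic for the synthetic CRC network. Order expresses precedence:
# tumor progression (abnormal proliferation concurrent with metastasis)
# must be matched before its component fates.
FATE apoptosis: APOP
FATE tumor_progression: PROLIF AND ONCO AND EMT
FATE abnormal_proliferation: PROLIF AND ONCO
FATE normal_proliferation: PROLIF
FATE metastasis: EMT
FATE arrest: ARREST OR SEN
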