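well_id,ph_category
CSW1.4,neutral
N08-C,neutral
CSW1.2,neutral
QV1.2,neutral
QV1.3,moderate
CSW1.5,moderate
CSWold,moderate
CSW1.3,moderate
N08-A,extreme
N08-B,extreme
QV1.1,extreme
CSW1.1,extreme
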