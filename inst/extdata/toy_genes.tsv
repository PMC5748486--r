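gene	category
APC	CRC-driver
KRAS	CRC-driver
TP53	CRC-driver
BRAF	other-driver
APC	druggable
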