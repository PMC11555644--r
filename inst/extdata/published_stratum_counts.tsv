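study	sex	n_case	n_ctrl
GliomaScan	male	749	687
GliomaScan	female	567	606
AGOG	male	346	962
AGOG	female	214	1275
GICC	male	2401	1377
GICC	female	1599	1034
UCSF_Mayo	male	1251	1134
UCSF_Mayo	female	890	755
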