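label,nps_per_ml,nps_per_well,conc_um
CO20,7.2e11,5.76e10,60
CO40,7.2e10,5.76e9,60
CO80,7.8e9,6.24e8,60
HM35,7.3e10,5.84e9,40
HM75,5.7e9,4.56e8,40
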