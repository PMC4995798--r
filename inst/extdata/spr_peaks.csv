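label,water_nm,ccm_nm
HM35,527,537
HM75,544,552
CO20,523,524
CO40,530,532
CO80,555,556
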