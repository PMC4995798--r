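label,condition,d_core_tem_nm,d_h_dls_nm,pdi,zeta_mV,d_hs_cls_nm,t_sed_s,rho_app_gcm3
HM35,ccm,29.6,69.7,0.29,,,42.1,3.30
HM75,ccm,68.9,101.9,0.16,,,10.3,6.21
CO20,ccm,15.7,35.8,0.11,,,138.0,4.32
CO40,ccm,35.5,66.5,0.16,,,31.5,5.00
CO80,ccm,72.8,116.7,0.09,,,7.1,6.72
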