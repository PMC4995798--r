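label,condition,d_core_tem_nm,d_h_dls_nm,pdi,zeta_mV,d_hs_cls_nm,t_sed_s,rho_app_gcm3
HM15,water,11.3,20.3,0.04,-37.0,7.8,,3.8
HM35,water,29.6,34.6,0.14,-40.3,29.7,28.9,13.6
HM75,water,68.9,71.8,0.24,-44.6,62.5,7.7,14.8
CO20,water,15.7,32.9,0.11,-16.1,17.1,97.5,6.0
CO40,water,35.5,54.4,0.12,-20.2,38.3,25.0,8.2
CO80,water,72.8,95.4,0.07,-25.1,75.1,5.3,12.4
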