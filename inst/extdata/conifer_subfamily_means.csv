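subfamily,DPM_um,DT_um,DPA_um,TO,MF,VE,Dh_um,TD_per_mm2,Tw_um,TSR,WD_g_cm3,RPA_MPa_s_m3,P50_abs_MPa,Ks_kg_m_s_MPa
Piceoideae,13.37,7.28,4.38,0.40,0.45,0.18,11.73,3960,2.68,0.69,0.59,3.06e8,4.11,0.28
Pinoideae,14.25,7.78,4.59,0.41,0.45,0.18,12.95,3240,2.53,0.32,0.49,2.66e8,3.09,0.31
Laricoideae,14.78,8.03,5.05,0.36,0.46,0.16,14.46,2470,2.36,0.48,0.50,1.97e8,3.35,0.58
Abietoideae,12.81,6.60,4.35,0.34,0.48,0.16,12.72,3460,2.50,0.46,0.54,3.12e8,3.81,0.31
Cupressoideae,9.48,4.11,2.69,0.34,0.57,0.19,11.97,3980,2.57,0.44,0.55,1.35e9,6.44,0.34
Taxodioideae,9.93,4.49,3.28,0.27,0.55,0.15,12.99,3290,2.64,0.47,0.51,7.27e8,4.04,0.27
Sequoioideae,12.39,5.73,4.14,0.27,0.54,0.14,15.40,2720,2.63,0.31,0.46,3.57e8,3.30,0.20
Taxaceae,11.15,4.84,2.98,0.38,0.57,0.22,11.36,4350,2.97,0.61,0.60,1.00e9,5.67,0.24
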