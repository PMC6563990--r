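x1	x2	tissue	E_FDR_r
delta_m_inf	delta_m_inf	healthy	0.0
delta_m_inf	delta_beta100	healthy	0.2544
delta_m_inf	delta_h	healthy	0.2060
delta_beta100	delta_m_inf	healthy	0.2261
delta_beta100	delta_beta100	healthy	0.0
delta_beta100	delta_h	healthy	0.4387
delta_h	delta_m_inf	healthy	0.1376
delta_h	delta_beta100	healthy	0.4062
delta_h	delta_h	healthy	0.0
delta_m_inf	delta_m_inf	cancer	0.0
delta_m_inf	delta_beta100	cancer	0.2867
delta_m_inf	delta_h	cancer	0.1801
delta_beta100	delta_m_inf	cancer	0.2173
delta_beta100	delta_beta100	cancer	0.0
delta_beta100	delta_h	cancer	0.4094
delta_h	delta_m_inf	cancer	0.1617
delta_h	delta_beta100	cancer	0.4451
delta_h	delta_h	cancer	0.0
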