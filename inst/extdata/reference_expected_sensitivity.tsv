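x1	x2	tissue	E_SE_r
delta_m_inf	delta_m_inf	healthy	1.0
delta_m_inf	delta_beta100	healthy	0.7739
delta_m_inf	delta_h	healthy	0.8624
delta_beta100	delta_m_inf	healthy	0.7456
delta_beta100	delta_beta100	healthy	1.0
delta_beta100	delta_h	healthy	0.5938
delta_h	delta_m_inf	healthy	0.7940
delta_h	delta_beta100	healthy	0.5613
delta_h	delta_h	healthy	1.0
delta_m_inf	delta_m_inf	cancer	1.0
delta_m_inf	delta_beta100	cancer	0.7827
delta_m_inf	delta_h	cancer	0.8383
delta_beta100	delta_m_inf	cancer	0.7133
delta_beta100	delta_beta100	cancer	1.0
delta_beta100	delta_h	cancer	0.5549
delta_h	delta_m_inf	cancer	0.8199
delta_h	delta_beta100	cancer	0.5906
delta_h	delta_h	cancer	1.0
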