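pair	tissue	E_S	E_SH
delta_beta100,delta_h	healthy	0.7946	0.5892
delta_beta100,delta_h	cancer	0.7897	0.5794
delta_beta100,delta_m_inf	healthy	0.8052	0.6104
delta_beta100,delta_m_inf	cancer	0.8016	0.6032
delta_m_inf,delta_h	healthy	0.8021	0.6042
delta_m_inf,delta_h	cancer	0.8060	0.6120
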