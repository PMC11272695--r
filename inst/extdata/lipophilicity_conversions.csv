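name,input_subtype,slope,intercept,citation
yun_logp,LogP,0.960,0.940,"Yun & Edginton 2013, LogP to membrane affinity regression (implementer-transcribed approximation)"
endo_logp,LogP,0.870,0.420,"Endo et al. 2011, LogP to liposome-water distribution regression (implementer-transcribed approximation)"
loidl_logd,LogD,0.900,0.520,"refit from Loidl-Stahlhofen et al. 2001 membrane-affinity data (synthetic refit; original data unavailable)"
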