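model,parameter,estimate,se
rate,rho,0.16978,0.013258
rate,t_max,22.13802,0.268383
rate,delta_t,5.67016,0.395566
dist,alpha,1.15460,0.036266
dist,beta,1.71717,0.119902
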