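model,parameter,estimate,se
rate,rho,0.151932200,0.019070840
rate,t_max,37.88922166,3.322196970
rate,delta_t,6.572996371,0.822062604
dist,alpha,1.121146325,0.010050286
dist,beta,3.155020615,0.121914537
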