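engine,n,m,rho,maf,slope,delta1,delta2,sigma_y,sigma,fwer,n_tests,n_reps,seed
slr,100,NA,NA,0.2,0.13,NA,NA,0.13,NA,0.05,1,1e+05,101
slr,1000,NA,NA,0.5,0.028,NA,NA,0.4,NA,0.05,1,1e+05,102
slr,500,NA,NA,0.3,0.065,NA,NA,0.4,NA,0.05,1,1e+05,103
slr,300,NA,NA,0.2,0.1,NA,NA,0.5,NA,0.05,1,1e+05,104
slr,500,NA,NA,0.1,0.1,NA,NA,0.4,NA,0.05,1000,1e+05,105
slr,800,NA,NA,0.05,0.08,NA,NA,0.4,NA,0.05,1,1e+05,106
anova,200,NA,NA,0.3,NA,0.13,0.13,NA,0.13,0.05,1,1e+05,201
anova,500,NA,NA,0.4,NA,0.05,0,NA,0.25,0.05,1,1e+05,202
anova,400,NA,NA,0.2,NA,0.08,0.06,NA,0.35,0.05,1,1e+05,203
anova,300,NA,NA,0.4,NA,-0.06,0.03,NA,0.3,0.05,1,1e+05,204
anova,600,NA,NA,0.5,NA,0.04,0.04,NA,0.3,0.05,1,1e+05,205
anova,500,NA,NA,0.2,NA,0.06,0.05,NA,0.35,0.05,1,1e+05,206
sc_lmm,50,100,0.3,0.2,0.1,NA,NA,0.5,NA,0.05,1,10000,301
sc_lmm,150,1,0,0.3,0.14,NA,NA,0.6,NA,0.05,1,10000,302
sc_lmm,100,200,0.8,0.5,0.2,NA,NA,0.7,NA,0.05,1,10000,303
sc_lmm,100,100,0.5,0.3,0.12,NA,NA,0.6,NA,0.05,1,10000,304
sc_lmm,80,50,0.1,0.2,0.05,NA,NA,0.5,NA,0.05,1,10000,305
sc_lmm,100,30,0.3,0.1,0.12,NA,NA,0.5,NA,0.05,100,10000,306
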