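name,model,neuron,source,ambiguous,theta1,theta2,theta3,theta4,K1,K2,tau_c,tau1,tau2,k,A,m,tau_act,beta_ratio,filter,scaling,wl_theta0,wl_theta1,wl_theta2,wl_theta3,fit_error
seti_animal_A_hatze,hatze_zakotnik,SETi,per_animal_fit,FALSE,101,2956,1858,34666,0.0177,0.000837,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.0877
seti_animal_B_hatze,hatze_zakotnik,SETi,per_animal_fit,FALSE,105,4970,3697,61239,0.0105,0.000203,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.1693
seti_animal_D_hatze,hatze_zakotnik,SETi,per_animal_fit,FALSE,72,2019,6770,70464,0.0130,0.000704,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.0498
zakotnik2006_mean_seti,hatze_zakotnik,SETi,published_mean,FALSE,79,2783,4919,78582,0.0146,0.00039,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
zakotnik2006_mean_seti_printed,hatze_zakotnik,SETi,published_mean_literal_decimals,TRUE,79,2783,4919,78.582,0.0146,0.00039,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
feti_animal_2_hatze,hatze_zakotnik,FETi,per_animal_fit,FALSE,28,1696,9303,71978,0.0470,0.0021,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.2706
feti_animal_3_hatze,hatze_zakotnik,FETi,per_animal_fit,FALSE,34,1687,5385,37357,0.0076,0.0026,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.4788
feti_animal_4_hatze,hatze_zakotnik,FETi,per_animal_fit,FALSE,51,1010,3577,120970,0.0106,0.0007,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.1582
seti_animal_A_wilson,wilson_nl,SETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.088,0.095,-0.027,1.45,47.65,2.34,NA,NA,NA,NA,NA,NA,NA,NA,0.0491
seti_animal_B_wilson,wilson_nl,SETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.059,0.186,-0.210,2.33,48.42,2.59,NA,NA,NA,NA,NA,NA,NA,NA,0.1119
seti_animal_D_wilson,wilson_nl,SETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.152,0.005,0.103,1.57,25.59,1.59,NA,NA,NA,NA,NA,NA,NA,NA,0.0400
wilson2013_mean_seti,wilson_nl,SETi,published_mean,FALSE,NA,NA,NA,NA,NA,NA,0.11,0.05,0.00,6.55,24.39,1.91,NA,NA,NA,NA,NA,NA,NA,NA,NA
feti_animal_2_wilson,wilson_nl,FETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.072,0.013,0.080,0.77,19.31,3.05,NA,NA,NA,NA,NA,NA,NA,NA,0.0560
feti_animal_3_wilson,wilson_nl,FETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.093,0.067,0.040,1.05,25.74,2.16,NA,NA,NA,NA,NA,NA,NA,NA,0.0509
feti_animal_4_wilson,wilson_nl,FETi,per_animal_fit,FALSE,NA,NA,NA,NA,NA,NA,0.083,0.069,0.019,1.08,30.12,3.37,NA,NA,NA,NA,NA,NA,NA,NA,0.0525
wilson2013_mean_feti,wilson_nl,FETi,published_mean,FALSE,NA,NA,NA,NA,NA,NA,0.070,0.083,0.10,0.57,5.8,1.8,NA,NA,NA,NA,NA,NA,NA,NA,NA
default_zajac,zajac,NA,package_default,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.04,0.2,NA,NA,NA,NA,NA,NA,NA
default_blumel,blumel,NA,package_default,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.998667,1,NA,NA,NA,NA,NA
default_wilson_linear,wilson_linear,NA,package_default,FALSE,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,1,0.317,0.00516,1.8e-05,NA
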