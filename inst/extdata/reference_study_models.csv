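table,predictor,coefficient,se,ratio,p_value
univariate_logistic,suv_max,0.16,0.095,1.2,0.10
univariate_logistic,suv_mean,0.34,0.15,1.4,0.02
univariate_logistic,suv_sd,1.5,0.54,4.4,0.0057
univariate_logistic,suv_p80,0.31,0.13,1.4,0.013
univariate_logistic,suv_p90,0.33,0.12,1.4,0.0061
univariate_logistic,suv_p95,0.33,0.12,1.4,0.0049
multiple_logistic,intercept,-6.1,1.7,NA,NA
multiple_logistic,suv_p95,0.40,0.13,1.5,0.0027
multiple_logistic,age,0.79,0.26,2.2,0.0026
multiple_logistic,v30,0.09,0.034,1.1,0.007
cox,suv_p95,0.18,0.057,1.2,0.002
cox,age,0.34,0.14,1.4,0.013
cox,v30,0.05,0.02,1.1,0.011
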