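stratum,quartile,cases,n,published_rr,published_ci_low,published_ci_high
underweight,Q1,27,178,1,NA,NA
underweight,Q2,34,191,1.17,0.74,1.86
underweight,Q3,56,205,1.80,1.19,2.72
underweight,Q4,93,228,2.69,1.84,NA
normal,Q1,500,3070,1,NA,NA
normal,Q2,720,3249,1.36,1.23,NA
normal,Q3,903,3380,1.64,1.49,NA
normal,Q4,1232,3471,NA,1.99,2.39
overweight,Q1,192,1003,1,NA,NA
overweight,Q2,213,972,1.14,0.96,1.36
overweight,Q3,215,828,1.36,1.14,1.61
overweight,Q4,223,661,1.76,1.49,2.08
obese,Q1,61,404,1,NA,NA
obese,Q2,68,326,1.38,1.01,1.89
obese,Q3,59,265,1.47,1.07,2.04
obese,Q4,78,230,2.25,1.68,3.01
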