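quartile,cases,n,published_rr,published_ci_low,published_ci_high
Q1,812,4879,1,NA,NA
Q2,1080,4948,1.31,1.21,1.42
Q3,1292,4898,1.58,1.47,1.71
Q4,1726,4857,2.14,1.98,2.30
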