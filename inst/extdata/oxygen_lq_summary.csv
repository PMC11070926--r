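# Published oxygen-ion LQ summaries per SOBP position: BED50, maximum RBE
# (zero fractional dose limit) and alpha/beta, with SE and 90% CL.
let_value,bed50,bed50_se,bed50_cl_low,bed50_cl_high,rbe_max,rbe_max_se,rbe_max_cl_low,rbe_max_cl_high,alpha_beta,ab_se,ab_cl_low,ab_cl_high
26,39.3,6.8,30.7,59.8,6.23,1.24,4.59,8.96,13.4,4.6,6.6,23.8
66,23.4,2.1,20.3,29.1,10.45,1.39,8.36,12.99,23.0,6.2,13.2,38.9
98,19.7,2.1,16.7,25.1,12.44,1.82,9.79,15.89,29.5,12.1,14.4,69.5
141,18.9,1.5,16.8,22.4,12.94,1.63,10.44,15.86,81.2,47.4,34.1,469.9
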