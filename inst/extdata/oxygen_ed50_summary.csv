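# Published oxygen-ion ED50 and RBE per SOBP position and schedule
# (rat cervical spinal cord, paresis grade II within 300 d).
# cl columns are 90% confidence limits; NA where the CL could not be
# calculated. in_sobp: FALSE marks the entrance-plateau position (35 mm).
let_value,depth,n_fractions,in_sobp,ed50,ed50_se,ed50_cl_low,ed50_cl_high,rbe,rbe_se,cl_low,cl_high
26,35,1,FALSE,17.2,0.3,16.5,17.9,1.43,0.05,1.34,1.51
66,100,1,TRUE,14.4,0.3,13.7,15.0,1.71,0.06,1.60,1.81
98,120,1,TRUE,13.5,0.4,12.7,14.4,1.82,0.08,1.69,1.96
141,127,1,TRUE,15.8,0.4,14.9,16.6,1.56,0.06,1.45,1.67
26,35,2,FALSE,21.7,0.4,20.9,22.4,1.58,0.04,1.51,1.65
66,100,2,TRUE,17.0,0.5,NA,NA,2.01,0.07,1.90,2.13
98,120,2,TRUE,15.5,0.5,NA,NA,2.21,0.08,2.08,2.35
141,127,2,TRUE,17.2,0.4,16.4,17.9,1.99,0.06,1.90,2.09
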