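# Photon reference-experiment summaries for the rat cervical spinal cord
# (paresis grade II within 300 d): ED50 per schedule, pooled BED50 and
# alpha/beta, each with SE and 90% confidence limits. These enter the RBE
# chain as constants; the photon raw data are external to this package.
quantity,value,se,cl_low,cl_high
ed50_1fx,24.5,0.8,23.3,26.7
ed50_2fx,34.3,0.7,32.9,36.6
bed50,244.9,24.3,208.2,293.3
alpha_beta,2.8,0.4,2.2,3.5
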