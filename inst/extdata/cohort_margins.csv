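group,n,female,white,age_mean,age_sd,bmi_mean,bmi_sd
none,1164,502,1086,63.39,10.32,26.30,4.64
current,185,131,167,58.66,8.76,26.75,5.36
remitted,968,628,893,60.47,9.42,26.34,4.77
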