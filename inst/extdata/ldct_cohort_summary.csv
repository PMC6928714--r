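clinic,n_ldct,updrs_off_mean,updrs_on_mean
1,53,54,27
2,49,51,34
3,49,41,18
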