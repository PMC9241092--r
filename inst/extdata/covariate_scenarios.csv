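covariate,level,affected_models,s1,s2,s3,s4,s5,s6
n_surveys,,,5,9,2,5,1,3
age_group,individual,both,1,1,1,1,1,1
education,individual,both,1,1,1,1,1,1
marital,individual,both,1,1,1,1,1,1
residence,individual,both,1,1,1,1,1,1
ipv_history,group,female_hiv,1,1,0,0,1,0
belief_fidelity,group,both,1,1,1,1,1,1
belief_beating_justified,group,both,1,1,1,1,1,1
partner_age_diff_large,group,female_hiv,1,1,1,1,0,0
alcohol_before_sex,group,male_hiv,1,0,1,0,0,0
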