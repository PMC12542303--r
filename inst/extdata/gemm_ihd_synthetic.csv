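# alpha: 1.6
# mu: 15.5
# nu: 36.8
# counterfactual_conc: 2.4
# source_version: synthetic-default-v1
cause,age_group,theta,theta_se
IHD,25-29,0.600,0.1000
IHD,30-34,0.520,0.0880
IHD,35-39,0.450,0.0760
IHD,40-44,0.390,0.0660
IHD,45-49,0.340,0.0570
IHD,50-54,0.300,0.0500
IHD,55-59,0.260,0.0440
IHD,60-64,0.230,0.0380
IHD,65-69,0.200,0.0330
IHD,70-74,0.180,0.0300
IHD,75-79,0.160,0.0270
IHD,80+,0.140,0.0240
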