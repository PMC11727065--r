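{"beta_sbp":[35.55,-2.81,-1.13,0.46,0.57,-4.58,0.83],"beta_dbp":[-11.3,1.1,30.6,-2.22,0.51,-3.4,0.19],"sigma_sbp":5,"sigma_dbp":4,"tau":0.5,"powers":{"BMI":[0.5,1],"Age":[0.5,1]},"error":"ald","term":["BMI^0.5","BMI","Age^0.5","Age","Ethnicity","Gender","MaritalStatus"],"seed":20240400,"n":400}
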