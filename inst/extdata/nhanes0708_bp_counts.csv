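response,factor,level,normal,pre_hypertension,hypertension
SBP,BMI,Underweight,37,16,12
SBP,BMI,Healthy,734,343,140
SBP,BMI,Overweight,781,565,232
SBP,BMI,Obese,415,414,166
SBP,BMI,Very obese,201,187,83
SBP,BMI,Morbidly obese,106,116,61
SBP,Age,20-29 years,493,164,15
SBP,Age,30-39 years,543,251,33
SBP,Age,40-49 years,460,285,78
SBP,Age,>=50 years,778,941,568
SBP,Ethnicity,Mexican American,456,279,105
SBP,Ethnicity,Other Hispanic,286,186,66
SBP,Ethnicity,Non-Hispanic white,1006,793,314
SBP,Ethnicity,Non-Hispanic black,425,324,189
SBP,Ethnicity,Other non-Hispanic race,101,59,20
SBP,Gender,Male,999,957,352
SBP,Gender,Female,1275,684,342
SBP,MaritalStatus,Married,1219,927,373
SBP,MaritalStatus,Widowed,84,103,92
SBP,MaritalStatus,Divorced,226,182,104
SBP,MaritalStatus,Separated,89,57,25
SBP,MaritalStatus,Never married,468,256,71
SBP,MaritalStatus,Living with partner,188,116,29
DBP,BMI,Underweight,49,12,4
DBP,BMI,Healthy,1025,148,44
DBP,BMI,Overweight,1265,243,70
DBP,BMI,Obese,772,168,55
DBP,BMI,Very obese,356,78,37
DBP,BMI,Morbidly obese,217,47,19
DBP,Age,20-29 years,619,47,6
DBP,Age,30-39 years,681,118,28
DBP,Age,40-49 years,584,173,66
DBP,Age,>=50 years,1800,358,129
DBP,Ethnicity,Mexican American,699,116,25
DBP,Ethnicity,Other Hispanic,444,70,24
DBP,Ethnicity,Non-Hispanic white,1687,327,99
DBP,Ethnicity,Non-Hispanic black,711,154,73
DBP,Ethnicity,Other non-Hispanic race,143,29,8
DBP,Gender,Male,1732,423,153
DBP,Gender,Female,1952,273,76
DBP,MaritalStatus,Married,2017,385,117
DBP,MaritalStatus,Widowed,231,38,10
DBP,MaritalStatus,Divorced,386,87,39
DBP,MaritalStatus,Separated,133,26,12
DBP,MaritalStatus,Never married,656,103,36
DBP,MaritalStatus,Living with partner,261,57,15
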