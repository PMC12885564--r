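model_id,feature,importance,metric,performance
m1,Blood Pressure,1,rank,
m1,Cholesterol,1,rank,
m2,Blood Pressure,2,rank,
m2,Cholesterol,8,rank,
m3,Blood Pressure,4,rank,
m3,Cholesterol,2,rank,
m4,Blood Pressure,1,rank,
m4,Cholesterol,15,rank,
m5,Blood Pressure,3,rank,
m5,Cholesterol,1,rank,
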