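animal_category,sector,sex,min_months,max_months
heifer_calf,dairy,female,0,3
weaned_heifer,dairy,female,4,9
maiden_heifer,dairy,female,10,15
in_calf_heifer,dairy,female,16,24
lactation_1,dairy,female,24,36
lactation_2,dairy,female,36,48
lactation_3,dairy,female,48,60
lactation_4plus,dairy,female,60,96
calf,beef,male,0,3
weaned,beef,male,4,9
in_calf_heifer_beef,beef,female,16,24
young_bull_feeder,beef,male,10,16
light_store,beef,male,10,16
forward_store,beef,male,17,24
parity_1,beef,female,24,36
parity_2,beef,female,36,48
parity_3,beef,female,48,60
parity_4plus,beef,female,60,96
finished,beef,male,20,30
cull_cow,beef,female,60,120
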