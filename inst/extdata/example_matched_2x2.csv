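covariate,a,b,c,d
male,169,128,159,138
insomnia,3,294,9,288
diabetes_mellitus,61,236,67,230
dyslipidemia,134,163,140,157
mental_behavioral_diseases,14,283,9,288
gastrointestinal_diseases,48,249,39,258
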