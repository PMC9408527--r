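#semantic=illness or injury,syntactic=noun
illness, fever, pain, injury, infection, flu, cold, fracture, accident,
sickness, cough, allergy, wound, headache, stomachache
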