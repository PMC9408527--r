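id,frames,question
Q1,frames/q1_communication.txt,"Does the text mention any difficulties in language communication?"
Q2,frames/q2_illness_reason.txt,"Does the text mention illness or injury as a reason for contact with a healthcare facility?"
Q3a,frames/q3a_physicians.txt,"Does the text mention any physician or physicians involved in providing health services?"
Q3b,frames/q3b_other_personnel.txt,"Does the text mention personnel other than physicians involved in providing health services?"
Q4,frames/q4_facility_change.txt,"Does the text mention seeking medical help in more than one healthcare facility?"
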