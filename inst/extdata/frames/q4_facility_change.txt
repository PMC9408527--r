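# seeking help in more than one facility
"another" ++ G:facility_noun
"other" ++ G:facility_noun
"second" ++ G:facility_noun
G:transfer_verb + G:facility_noun
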