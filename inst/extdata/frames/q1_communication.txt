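# language-communication difficulty
G:communication_noun + G:difficulty_noun
G:difficulty_noun + G:communication_noun
G:negation_word ++ G:communication_verb
"difficult" ++ "to" ++ G:communication_verb
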