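# illness or injury as the reason for the visit
G:illness_noun
"felt" ++ "sick"
"was" ++ "injured"
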