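#semantic=negation,syntactic=function
not, no, never, didn't, couldn't, cannot, can't, don't, doesn't, wasn't
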