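#semantic=language and communication,syntactic=noun
language, english, polish, communication, translator, interpreter, words, accent
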