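# negation words: flip the next opinion word
not
never
no
hardly
barely
cannot
dont
didnt
doesnt
isnt
wasnt
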