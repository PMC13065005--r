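# strong intensifiers: boost the next opinion word
truly
extremely
really
absolutely
incredibly
highly
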