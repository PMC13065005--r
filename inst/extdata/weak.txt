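# weak modifiers: attenuate the next opinion word
quite
somewhat
slightly
fairly
rather
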