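# birth control condition vocabulary
acne
cramps
bleeding
spotting
period
periods
mood swings
weight gain
hormones
side effects
side affects
nausea
headache
hair loss
hair
scalp
libido
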