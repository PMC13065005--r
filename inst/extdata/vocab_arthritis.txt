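# rheumatoid arthritis condition vocabulary
pain
joint pain
swelling
stiffness
inflammation
side effects
side affects
fatigue
nausea
stomach
vomiting
diarrhea
dose
arthritis
flare
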