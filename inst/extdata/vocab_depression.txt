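# depression condition vocabulary (curated word list, one term per line)
anxiety
depression
mood
mood swings
feelings
insomnia
nausea
headache
fatigue
dizziness
appetite
libido
energy
pain
side effects
side affects
panic attacks
weight gain
brain zaps
sleep
stress
sex drive
jitters
yawning
stomach
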