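term	pos	pos_score	neg_score	obj_score
lucky	ADJ	0.7	0	0.3
positive	ADJ	0.7	0	0.3
good	ADJ	0.75	0	0.25
wonderful	ADJ	0.8	0.1	0.1
helpful	ADJ	0.8	0.05	0.15
effective	ADJ	0.75	0.1	0.15
optimistic	ADJ	0.75	0	0.25
better	ADJ	0.65	0.1	0.25
focused	ADJ	0.65	0.05	0.3
awful	ADJ	0.1	0.8	0.1
terrible	ADJ	0.05	0.85	0.1
bad	ADJ	0.1	0.7	0.2
worse	ADJ	0.1	0.65	0.25
worried	ADJ	0.1	0.7	0.2
bloated	ADJ	0.05	0.75	0.2
embarrassing	ADJ	0.05	0.7	0.25
well	ADV	0.7	0.1	0.2
badly	ADV	0.1	0.7	0.2
huge	ADJ	0.3	0.1	0.6
daily	ADJ	0	0	1
general	ADJ	0.1	0.1	0.8
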