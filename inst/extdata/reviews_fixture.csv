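"review_id","drugName","condition","review"
"syn0001","betazol","depression","my anxiety since last week . my panic attacks feels never effective ."
"syn0002","deltaprex","depression","my hormonal anxiety since last week . my side effects feels awful ."
"syn0003","alphadrin","depression","my side affects since last week . my chronic headache feels awful my coffee table ."
"syn0004","alphadrin","depression","my depressive nausea feels bad my traffic . my physical anxiety feels bad ."
"syn0005","gammaline","depression","my panic attacks since last week my weather . my anxiety feels good ."
"syn0006","alphadrin","depression","my brain zaps feels awful my garden . my brain zaps feels bad my coffee table ."
"syn0007","deltaprex","depression","my hormonal anxiety feels terrible . my mood swings feels extremely awful my coffee table ."
"syn0008","alphadrin","depression","my weight gain since last week . my energy feels awful my phone screen ."
"syn0009","alphadrin","depression","my libido since last week my parking lot . my pain feels never good ."
"syn0010","deltaprex","depression","my side affects since last week . my fatigue since last week ."
"syn0011","alphadrin","depression","my side effects feels truly effective my weather . my mental dizziness feels terrible ."
"syn0012","betazol","depression","my insomnia feels terrible my hormonal ceiling . my appetite feels terrible ."
"syn0013","gammaline","depression","my dizziness since last week . my dizziness feels never terrible ."
"syn0014","gammaline","depression","my mood swings since last week . my hormonal energy since last week ."
"syn0015","deltaprex","depression","my hormonal libido since last week . my side effects feels never good ."
"syn0016","alphadrin","depression","my fatigue since last week . my nausea feels bad ."
"syn0017","alphadrin","depression","my chronic pain since last week my sofa . my headache feels bad ."
"syn0018","betazol","depression","my chronic insomnia feels awful . my libido since last week ."
"syn0019","deltaprex","depression","my hormonal dizziness feels never good . my side effects since last week ."
"syn0020","betazol","depression","my panic attacks feels not wonderful my coffee table . my side effects since last week ."
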