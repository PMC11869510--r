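scenario,women_screened,screens,recalls_no_cancer,biopsies,negative_biopsies,invasive_dx,screen_detected_dx,bc_deaths
SQ,5910283,69573861,5461199,939498,638960,660943,300538,125836
A40,6684096,78816485,6185564,1036900,723711,662747,313189,124934
B40,6684096,74373190,5874533,994839,687320,661355,307519,125254
A45,6305809,74180113,5823189,989508,681313,661969,308195,125297
B45,6305809,71972882,5668683,967694,663236,661186,304458,125399
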