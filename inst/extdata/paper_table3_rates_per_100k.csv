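scenario,recalls_no_cancer,biopsies,negative_biopsies,invasive_dx,screen_detected_dx,bc_deaths
SQ,7849,1350,918.4,950,432,180.9
A40,7848,1316,918.2,841,397,158.5
B40,7899,1338,924.2,889,413,168.4
A45,7850,1334,918.5,892,416,168.9
B45,7876,1345,921.5,919,423,174.2
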