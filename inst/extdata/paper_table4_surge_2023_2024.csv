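scenario,screens,screens_pct,recalls_no_cancer,recalls_no_cancer_pct,biopsies,biopsies_pct,negative_biopsies,negative_biopsies_pct,screen_detected_dx,screen_detected_dx_pct
SQ,89883,3.0,6606,2.9,1109,2.8,773,2.9,337,2.6
A40,742176,25.1,117496,51.1,16103,40.6,13747,51.1,2356,18.4
B40,742176,25.1,117496,51.1,16103,40.6,13747,51.1,2356,18.4
A45,406828,13.8,60486,26.3,8663,21.8,7077,26.3,1586,12.4
B45,406828,13.8,60486,26.3,8663,21.8,7077,26.3,1586,12.4
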