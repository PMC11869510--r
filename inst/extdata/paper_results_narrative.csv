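scenario,outcome,printed_value,printed_pct
A40,screens,9240000,13.3
A40,recalls_no_cancer,724000,13.3
A40,biopsies,97400,10.4
A40,negative_biopsies,84800,13.3
A40,invasive_dx,1804,0.27
A40,screen_detected_dx,12700,4.2
A40,deaths_averted,902,-0.72
A40,stage_0,1459,NA
A40,stage_I,4997,NA
A40,stage_II,-1475,-0.57
A40,stage_III,-1303,-1.5
A40,stage_IV,-415,-1.2
B40,screens,4800000,6.9
B40,recalls_no_cancer,413000,7.6
B40,biopsies,55300,5.9
B40,negative_biopsies,48400,7.6
B40,invasive_dx,412,0.06
B40,screen_detected_dx,6981,2.3
B40,deaths_averted,582,-0.46
B40,stage_II,-867,-0.33
B40,stage_III,-856,-0.98
B40,stage_IV,-258,-0.77
A45,screens,4610000,6.6
A45,recalls_no_cancer,362000,6.6
A45,biopsies,50000,5.3
A45,negative_biopsies,42400,6.6
A45,invasive_dx,1026,0.16
A45,screen_detected_dx,7657,2.5
A45,deaths_averted,538,-0.43
A45,stage_II,-913,-0.35
A45,stage_III,-759,-0.87
A45,stage_IV,-234,-0.71
B45,screens,2400000,3.4
B45,recalls_no_cancer,207000,3.8
B45,biopsies,28200,3.0
B45,negative_biopsies,24300,3.8
B45,invasive_dx,242,0.04
B45,screen_detected_dx,3920,1.3
B45,deaths_averted,436,-0.35
B45,stage_II,-538,-0.21
B45,stage_III,-458,-0.53
B45,stage_IV,-202,-0.61
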