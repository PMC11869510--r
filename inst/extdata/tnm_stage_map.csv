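kind,t_cat,node_positive,metastasis,stage
DCIS,any,FALSE,FALSE,0
invasive,T1,FALSE,FALSE,I
invasive,T1,TRUE,FALSE,II
invasive,T2,FALSE,FALSE,II
invasive,T2,TRUE,FALSE,II
invasive,T3,FALSE,FALSE,II
invasive,T3,TRUE,FALSE,III
invasive,any,any,TRUE,IV
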