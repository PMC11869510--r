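scenario,stage,count,pct
SQ,0,61214,8.48
SQ,I,281197,38.94
SQ,II,259398,35.92
SQ,III,87051,12.05
SQ,IV,33298,4.61
A40,0,62673,8.64
A40,I,286194,39.45
A40,II,257922,35.55
A40,III,85748,11.82
A40,IV,32883,4.53
B40,0,61706,8.53
B40,I,283590,39.22
B40,II,258531,35.76
B40,III,86195,11.92
B40,IV,33039,4.57
A45,0,62070,8.57
A45,I,284129,39.24
A45,II,258485,35.70
A45,III,86292,11.92
A45,IV,33063,4.57
B45,0,61370,8.49
B45,I,282637,39.12
B45,II,258859,35.83
B45,III,86593,11.98
B45,IV,33096,4.58
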