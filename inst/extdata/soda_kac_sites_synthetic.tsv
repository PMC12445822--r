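species	position
Hs	26
Hs	34
Hs	42
Hs	125
Hs	133
Hs	60
Hs	75
Hs	90
Hs	155
Tb	30
Tb	121
Tb	129
Tb	60
Dm	38
Dm	137
Dm	60
Dm	75
Dm	170
Ec	26
Ec	75
Ec	90
Ec	155
Ec	185
Af	42
Af	60
Af	170
Af	185
At	133
At	75
Dr	34
Dr	155
Ts	60
Ts	90
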