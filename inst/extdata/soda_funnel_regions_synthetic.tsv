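species	start	end
Hs	25	45
Hs	120	140
Tb	25	45
Tb	120	140
Dm	25	45
Dm	120	140
Ec	25	45
Ec	120	140
Af	25	45
Af	120	140
At	25	45
At	120	140
Dr	25	45
Dr	120	140
Ts	25	45
Ts	120	140
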