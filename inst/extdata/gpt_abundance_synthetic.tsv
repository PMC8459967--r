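grain	gpt	abundance
wheat	alpha_gliadin	0.30
wheat	gamma_gliadin	0.25
barley	b_hordein	0.45
barley	c_hordein	0.25
rye	gamma_secalin	0.40
rye	omega_secalin	0.20
oat	avenin_a	0.60
oat	avenin_b	0.40
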