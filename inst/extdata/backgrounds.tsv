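metal	background	source
Cd	0.11	regional_background
Cu	22.3	back_solved_from_printed_pli
Pb	20.78	regional_background
Zn	62.6	back_solved_from_printed_pli
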