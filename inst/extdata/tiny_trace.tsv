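# {"sample_rate_hz":1000,"trap_stiffness_a_pn_per_nm":0.06,"trap_stiffness_b_pn_per_nm":0.07,"molecule_id":"tiny","condition":"handwritten","source":"imported","seed":null}
time_s	bead_a_nm	bead_b_nm
0.000000	1.5000	-0.5000
0.001000	2.2500	0.7500
0.002000	-1.0000	3.0000
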