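sample_id	compound	dose_level	exposure_time	organ	species	platform	test_type	control_group
c1	cpdA	Control	4 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|4 day
c2	cpdA	Control	4 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|4 day
m1	cpdA	Middle	4 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|4 day
m2	cpdA	Middle	4 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|4 day
c3	cpdA	Control	8 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|8 day
c4	cpdA	Control	8 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|8 day
m3	cpdA	Middle	8 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|8 day
m4	cpdA	Middle	8 day	liver	rat	Rat230_2	in_vivo	cpdA|liver|8 day
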