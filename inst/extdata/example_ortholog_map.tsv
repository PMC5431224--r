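set_id	platform	probe_id
OS1	Rat230_2	P00001
OS1	HG-U133_Plus_2	HP00001
OS2	Rat230_2	P00002
OS2	HG-U133_Plus_2	HP00002
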