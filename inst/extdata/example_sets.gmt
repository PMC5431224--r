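responders	synthetic example category	P00001	P00002	P00003
housekeeping	synthetic example category	P00004	P00005	P00006
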