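complex_id	members
CPX1	P00001;P00002
CPX2	P00003;P00004
CPX3	P00001;P00003
CPX3b	P00001;P00003
CPX4	P00005;P99999
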