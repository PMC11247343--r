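level	serious	non_serious
female	500	293
male	6	1
unknown	11	17
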