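level	serious	non_serious
<40	18	5
40-64	171	96
>=65	205	138
unknown	123	71
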