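drug	category	count
palbociclib	hospitalization	210
palbociclib	death	50
palbociclib	life_threatening	4
palbociclib	disability	0
palbociclib	others	204
palbociclib	unknown	424
ribociclib	hospitalization	152
ribociclib	death	62
ribociclib	life_threatening	11
ribociclib	disability	3
ribociclib	others	92
ribociclib	unknown	17
abemaciclib	hospitalization	9
abemaciclib	death	9
abemaciclib	life_threatening	6
abemaciclib	disability	1
abemaciclib	others	14
abemaciclib	unknown	13
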