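drug	category	level	count
palbociclib	sex	female	838
palbociclib	sex	male	10
palbociclib	sex	unknown	44
palbociclib	age_band	<40	24
palbociclib	age_band	40-64	323
palbociclib	age_band	>=65	415
palbociclib	age_band	unknown	130
palbociclib	year	2015	21
palbociclib	year	2016	45
palbociclib	year	2017	152
palbociclib	year	2018	134
palbociclib	year	2019	130
palbociclib	year	2020	122
palbociclib	year	2021	120
palbociclib	year	2022	168
palbociclib	country	united states	768
palbociclib	country	germany	5
palbociclib	country	united kingdom	9
palbociclib	country	argentina	32
palbociclib	country	canada	7
palbociclib	country	puerto rico	12
palbociclib	country	japan	9
palbociclib	country	other	50
ribociclib	sex	female	324
ribociclib	sex	male	7
ribociclib	sex	unknown	6
ribociclib	age_band	<40	10
ribociclib	age_band	40-64	83
ribociclib	age_band	>=65	115
ribociclib	age_band	unknown	129
ribociclib	year	2017	10
ribociclib	year	2018	40
ribociclib	year	2019	58
ribociclib	year	2020	67
ribociclib	year	2021	93
ribociclib	year	2022	69
ribociclib	country	united states	60
ribociclib	country	germany	56
ribociclib	country	united kingdom	40
ribociclib	country	argentina	8
ribociclib	country	canada	12
ribociclib	country	other	161
abemaciclib	sex	female	44
abemaciclib	sex	male	0
abemaciclib	sex	unknown	8
abemaciclib	age_band	<40	1
abemaciclib	age_band	40-64	8
abemaciclib	age_band	>=65	15
abemaciclib	age_band	unknown	28
abemaciclib	year	2019	9
abemaciclib	year	2020	12
abemaciclib	year	2021	21
abemaciclib	year	2022	10
abemaciclib	country	united states	35
abemaciclib	country	germany	3
abemaciclib	country	united kingdom	3
abemaciclib	country	japan	3
abemaciclib	country	other	8
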