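country	subregion_code	subregion
CHN	EA	Eastern Asia
JPN	EA	Eastern Asia
KOR	EA	Eastern Asia
MNG	EA	Eastern Asia
USA	NA	Northern America
CAN	NA	Northern America
SWE	NE	Northern Europe
DNK	NE	Northern Europe
NOR	NE	Northern Europe
FIN	NE	Northern Europe
GBR	NE	Northern Europe
IRL	NE	Northern Europe
EST	NE	Northern Europe
ISL	NE	Northern Europe
ITA	SE	Southern Europe
ESP	SE	Southern Europe
PRT	SE	Southern Europe
GRC	SE	Southern Europe
HRV	SE	Southern Europe
SVN	SE	Southern Europe
DEU	WE	Western Europe
FRA	WE	Western Europe
NLD	WE	Western Europe
BEL	WE	Western Europe
AUT	CE	Central Europe
HUN	CE	Central Europe
POL	CE	Central Europe
CZE	CE	Central Europe
SVK	CE	Central Europe
LUX	WE	Western Europe
CHE	WE	Western Europe
RUS	EE	Eastern Europe
IND	SA	Southern Asia
BGD	SA	Southern Asia
PAK	SA	Southern Asia
IDN	SEA	South-eastern Asia
MYS	SEA	South-eastern Asia
SGP	SEA	South-eastern Asia
PHL	SEA	South-eastern Asia
VNM	SEA	South-eastern Asia
THA	SEA	South-eastern Asia
ISR	WA	Western Asia
KAZ	CA	Central Asia
FJI	OC	Melanesia
AUS	ANZ	Australia and New Zealand
NZL	ANZ	Australia and New Zealand
TZA	AF	Eastern Africa
MDG	AF	Eastern Africa
ETH	AF	Eastern Africa
GHA	WAF	Western Africa
SLV	CAM	Central America
MEX	CAM	Central America
PER	SAM	South America
BRA	SAM	South America
COL	SAM	South America
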