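id	name	equation	lb	ub	objective
EX_CH4	methane exchange	ch4 ->	-1000	1000	0
EX_O2	oxygen exchange	o2 ->	-1000	1000	0
EX_CO2	carbon dioxide exchange	co2 ->	-1000	1000	0
EX_H2O	water exchange	h2o ->	-1000	1000	0
PMMO	particulate methane monooxygenase	ch4 + o2 + qh2 -> ch3oh + h2o + q	0	1000	0
XOXF	XoxF methanol dehydrogenase	ch3oh + 2 cytx_ox -> hcho + 2 cytx_red	0	1000	0
MXALa	XoxF-linked formaldehyde oxidation to formate	hcho + h2o + 2 cytx_ox -> chooh + 2 cytx_red	0	1000	0
H4MPT	H4MPT-linked formaldehyde oxidation (lumped) [lumped]	hcho + nad -> chooh + nadh	0	1000	0
FDH	formate dehydrogenase	chooh + nad -> co2 + nadh	0	1000	0
RUMP	RuMP assimilation to pyruvate (lumped) [lumped]	3 hcho + adp + pi + nad -> pyr + atp + nadh	0	1000	0
H4F_RECLAIM	H4folate-linked formate reclaim (lumped) [lumped]	chooh + atp + nadh -> hcho + adp + pi + nad + h2o	0	1000	0
NDH_Q	NADH:quinone oxidoreductase	nadh + q -> nad + qh2	0	1000	0
ETC_NADH	NADH respiration (lumped ETC) [lumped]	nadh + 0.5 o2 + 1.5 adp + 1.5 pi -> nad + h2o + 1.5 atp	0	1000	0
ETC_CYTM	MxaFI-cytochrome respiration (lumped ETC) [lumped]	2 cytm_red + 0.5 o2 + adp + pi -> 2 cytm_ox + h2o + atp	0	1000	0
ETC_CYTX	XoxF-cytochrome respiration (lumped ETC) [lumped]	2 cytx_red + 0.5 o2 + adp + pi -> 2 cytx_ox + h2o + atp	0	1000	0
QRED_CYTX	cytochrome-to-quinone electron transfer (XoxF pool)	2 cytx_red + q -> 2 cytx_ox + qh2	0	1000	0
BIOMASS	biomass equation (lumped) [lumped]	pyr + 2.75 atp + 0.3 nadh -> biomass + 2.75 adp + 2.75 pi + 0.3 nad	0	1000	1
NGAM	non-growth-associated maintenance	atp -> adp + pi	0	1000	0
# metabolites
id	formula	pseudo
ch4	C1H4	0
o2	O2	0
co2	C1O2	0
h2o	H2O1	0
ch3oh	C1H4O1	0
hcho	C1H2O1	0
chooh	C1H2O2	0
pyr	C3H4O3	0
atp		1
adp		1
pi		1
nad		1
nadh	H2	1
q		1
qh2	H2	1
cytm_ox		1
cytm_red	H1	1
cytx_ox		1
cytx_red	H1	1
biomass	C3 [exchange]	1
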