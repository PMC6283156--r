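toxin	class	IVL	IVR	V
cadmium	heavy metal	0	0	0
carmustine	chemotherapeutic	1	0	1
chlorothalonil	pesticide	2	1	1
chlorpyrifos	pesticide	1	1	0
cisplatin	chemotherapeutic	2	1	2
copper	heavy metal	2	0	0
diquat	pesticide	0	0	0
fluoxetine	neuropharmaceutical	1	2	0
FUdR	chemotherapeutic	1	1	0
irinotecan	chemotherapeutic	0	1	2
mechlorethamine	chemotherapeutic	0	0	1
paraquat	pesticide	0	0	1
silver	heavy metal	3	0	1
topotecan	chemotherapeutic	1	0	0
tunicamycin	chemotherapeutic	2	0	0
vincristine	chemotherapeutic	2	1	0
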