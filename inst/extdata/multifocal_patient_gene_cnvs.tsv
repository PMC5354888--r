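sample	gene	direction
pancreas	MDM2	gain
pancreas	VHL	loss
pancreas	PLA2G1B	loss
pancreas	LIMK1	loss
pancreas	KEAP1	loss
biliary_duct	MDM2	gain
biliary_duct	VHL	loss
biliary_duct	PLA2G1B	loss
biliary_duct	LIMK1	loss
biliary_duct	KEAP1	loss
biliary_duct	CDK4	gain
biliary_duct	GLI1	gain
omentum	MDM2	gain
omentum	VHL	loss
omentum	PLA2G1B	loss
omentum	LIMK1	loss
omentum	KEAP1	loss
omentum	CDK4	gain
omentum	GLI1	gain
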