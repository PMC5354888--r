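lesion	chrom	start	end
pancreas	chrX	177942	2686899
biliary_duct	chrX	177942	2686899
biliary_duct	chr4	143211964	146188881
biliary_duct	chr12	57810254	58498926
biliary_duct	chr13	48964265	49017901
biliary_duct	chr13	86031023	90196888
biliary_duct	chr16	30095734	35271725
biliary_duct	chrY	2660163	28799935
omentum	chr4	143211964	146188881
omentum	chr12	57810254	58498926
omentum	chr13	48964265	49017901
omentum	chr13	86031023	90196888
omentum	chr16	30095734	35271725
omentum	chrY	2660163	28799935
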