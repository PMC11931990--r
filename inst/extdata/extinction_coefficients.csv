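species,wavelength_nm,epsilon_m1cm1
Agp1 apoprotein,280,100000
Agp1-PCM apoprotein,280,78400
Agp1 Pr holoprotein,700,90000
Agp2 apoprotein,280,81300
Agp2-PCM apoprotein,280,57900
Agp2 HK+RR,280,23600
Agp2 Pfr holoprotein,750,45000
free biliverdin (methanol/HCl),696,30800
free Atto-495,495,80000
free Atto-565,565,120000
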