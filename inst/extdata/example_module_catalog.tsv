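module	process	enzymes	key_enzymes
M_WL	wood_ljungdahl	cooS,acsB,acsC,acsD,acsE,fdhA,fhs,folD,metF,cdhD	cooS,acsB
M_rTCA	reverse_tca	aclA,aclB,korA,korB,frdA,frdB,sdhA,mdh,fumA,icd	aclA,aclB
M_CBB	calvin_benson_bassham	rbcL,rbcS,prkB,cbbP,gapA,pgk,fbp,tktA,rpiA,rpe	rbcL,prkB
M_O2	oxygen_respiration	coxA,coxB,coxC,ccoN,ccoO,cyoA,cyoB,petA,petB,qcrA	coxA
M_SOX	sulfide_oxidation	sqr,fccA,fccB,soxA,soxB,soxC,soxY,soxZ,dsrA,dsrB	sqr
M_NIF	nitrogen_fixation	nifH,nifD,nifK,nifE,nifN,nifB,nifQ,nifV,nifS,nifU	nifH,nifD,nifK
M_HYD	hydrogen_oxidation	hyaA,hyaB,hybC,hupL,hupS,hoxF,hoxH,hoxU,hoxY,hydA	hyaA,hyaB
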