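program_version,species,breathing_pattern,inhalability_adjustment,substance,mmad_um,gsd,density_g_cm3,alveolar_fraction,head_tb_fraction,source
MPPD 2.0,rat,nasal,off,generic,1.8,2,1,0.075,0.333333333333,"MPPD 2.0 default settings (inhalability adjustment off); reproduces the 7.5% rat fraction of Pauluhn (2011); head+TB 33% implies the 3/2 extrathoracic factor"
MPPD 2.0,rat,nasal,on,generic,1.8,2,1,0.063,0.25,"MPPD 2.0 with inhalability adjustment on, as recommended by MAK and Oller & Oberdoerster; head+TB 25% implies the 4/3 factor"
MPPD 2.11,rat,nasal,on,generic,1.8,2,1,0.033,NA,"MPPD 2.11 with inhalability adjustment on; about half the 2.0 value at identical inputs"
MPPD 2.0,human,Oronasal-Mouth Breather,na,generic,1.8,2,1,0.164,NA,"MPPD 2.0, Oronasal-Mouth Breather; reproduces the 16.4% human fraction of Pauluhn (2011)"
MPPD 2.11,human,Oronasal-Mouth Breather,na,generic,1.8,2,1,0.157,NA,"MPPD 2.11, Oronasal-Mouth Breather"
MPPD 2.0,human,Oronasal-Normal Augmenter,na,generic,1.8,2,1,0.084,NA,"MPPD 2.0, Oronasal-Normal Augmenter (MAK-recommended breathing pattern)"
MPPD 2.11,human,Oronasal-Normal Augmenter,na,generic,1.8,2,1,0.088,NA,"MPPD 2.11, Oronasal-Normal Augmenter"
MPPD 2.0,human,Oronasal-Normal Augmenter,na,toner,NA,NA,1.2,0.0701,NA,"MAK-published human alveolar fraction for toner dust (Muhle et al. substance data)"
MPPD 2.0,human,Oronasal-Normal Augmenter,na,TiO2,NA,NA,4.3,0.0872,NA,"MAK-published human alveolar fraction for TiO2 dust (Muhle et al. substance data)"
MPPD 2.0,rat,nasal,on,toner,NA,NA,1,0.040,NA,"MPPD 2.0 density sweep at the toner size distribution, density 1 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,1.2,0.040,NA,"MPPD 2.0 density sweep, toner true density 1.2 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,2,0.041,NA,"MPPD 2.0 density sweep, density 2 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,3,0.042,NA,"MPPD 2.0 density sweep, density 3 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,4,0.042,NA,"MPPD 2.0 density sweep, density 4 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,4.3,0.0425,NA,"MPPD 2.0 density sweep at the TiO2 density 4.3 g/cm^3"
MPPD 2.0,rat,nasal,on,toner,NA,NA,5,0.042,NA,"MPPD 2.0 density sweep, density 5 g/cm^3"
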