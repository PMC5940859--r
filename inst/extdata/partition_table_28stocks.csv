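stock,region,habitat,fracFishing,fracShared,fracTemperature,totalAdjR2,sigFishing,sigTemperature,lag
Atheresthes_stomias_WestUS,WestUS,benthic,0.211,0.000,0.070,0.262,**,*,3
Sebastes_goodie_WestUS,WestUS,demersal,0.176,0.000,0.000,0.173,**,,0
Sebastes_crameri_WestUS,WestUS,demersal,0.012,0.000,0.030,0.029,,,3
Microstomus_pacificus_WestUS,WestUS,benthic,0.038,0.001,0.094,0.134,,*,0
Parophrys_vetulus_WestUS,WestUS,benthic,0.000,0.005,0.021,0.009,,,1
Ophiodon_elongatus_WestUS,WestUS,demersal,0.214,0.000,0.058,0.253,**,**,3
Sebastolobus_altivelis_WestUS,WestUS,demersal,0.391,0.000,0.006,0.392,**,,3
Eopsetta_jordani_WestUS,WestUS,benthic,0.093,0.000,0.005,0.093,**,,0
Sardinops_sagax_WestUS,WestUS,pelagic,0.033,0.000,0.035,0.057,,,1
Sebastes_diploproa_WestUS,WestUS,demersal,0.122,0.000,0.015,0.110,*,,0
Sebastes_ruberrimus_WestUS,WestUS,demersal,0.312,0.045,0.040,0.398,**,,1
Gadus_chalcogramma_AlaskaAI,Alaska,pelagic,0.000,0.000,0.368,0.266,,,0
Gadus_chalcogramma_AlaskaGOA,Alaska,pelagic,0.000,0.042,0.000,0.000,,,0
Hippoglossoides_elassodon_AlaskaEBS,Alaska,benthic,0.000,0.000,0.064,0.025,,,3
Hippoglossoides_elassodon_AlaskaGOA,Alaska,benthic,0.134,0.000,0.000,0.109,*,,1
Gadus_macrocephalus_AlaskaEBS,Alaska,demersal,0.071,0.000,0.034,0.104,*,,1
Gadus_macrocephalus_AlaskaGOA,Alaska,demersal,0.003,0.022,0.000,0.000,,,0
Glyptocephalus_zachirus_AlaskaGOA,Alaska,benthic,0.312,0.000,0.059,0.226,,,0
Gadus_morhua_NorthSea,NorthSea,demersal,0.067,0.078,0.094,0.239,*,**,1
Melanogrammus_aeglefinus_NorthSea,NorthSea,demersal,0.139,0.000,0.011,0.116,**,,3
Clupea_harengus_NorthSea,NorthSea,pelagic,0.003,0.009,0.001,0.013,,,1
Scomber_scombrus_NorthSea,NorthSea,pelagic,0.000,0.011,0.000,0.000,,,0
Trisopterus_esmarkii_NorthSea,NorthSea,pelagic,0.000,0.000,0.001,0.000,,,0
Pleuronectes_platessa_NorthSea,NorthSea,benthic,0.292,0.112,0.037,0.440,**,*,0
Pollachius_virens_NorthSea,NorthSea,demersal,0.027,0.042,0.037,0.106,,,0
Solea_solea_NorthSea,NorthSea,benthic,0.000,0.012,0.072,0.078,,*,3
Sprattus_sprattus_NorthSea,NorthSea,pelagic,0.025,0.000,0.102,0.108,,**,0
Merlangius_merlangius_NorthSea,NorthSea,demersal,0.372,0.000,0.001,0.351,,,1
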