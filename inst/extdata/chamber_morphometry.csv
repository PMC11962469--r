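species,chamber_diameter_um,chamber_diameter_sd,apopyle_diameter_um,apopyle_diameter_sd,apopyle_area_um2,theta_a_reported,choanocytes_per_chamber,choanocytes_sd
Ephydatia muelleri,34.7,5.0,18.1,4.3,NA,32.2,112,31
Haliclona urceolus,30,NA,14,NA,NA,27.8,80,NA
Haliclona permollis,30,NA,14,NA,NA,27.8,95,NA
Aphrocallistes vastus,56,NA,26,NA,NA,27.7,260,NA
Neopetrosia problematica,23.3,NA,16.0,NA,NA,43.4,80,NA
Haliclona mollis,28.5,NA,14.1,NA,NA,29.7,139,NA
Tethya californiana,21.1,NA,0.90,NA,NA,2.44,99,NA
Callyspongia vaginalis,19.7,NA,5.97,NA,NA,17.6,93,NA
Cliona delitrix,16.0,NA,4.23,NA,NA,15.3,50,NA
Amorphinopsis foetida,17.46,0.13,NA,NA,124.11,46.1,84.11,3.02
Callyspongia sp.,19.35,0.2,NA,NA,168.54,49.2,121.11,4.33
Haliclona sp.,19.69,0.23,NA,NA,113.21,37.6,68.83,2.82
Ircinia fusca,30.68,0.29,NA,NA,211.25,32.3,120.35,8.98
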