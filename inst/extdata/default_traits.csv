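taxon_code,m,d,g,brc
ACR_BRA,1.30,1.30,1.10,NA
ACR_TAB,1.15,1.35,0.90,NA
ACR_PAL,1.10,1.45,0.80,NA
POR_MAS,1.00,1.30,1.00,NA
POR_BRA,1.20,1.25,0.90,NA
POR_RUS,1.10,1.25,0.85,NA
MON_ENC,0.80,1.50,0.50,NA
POC_BRA,1.20,1.40,0.85,NA
FAV_MAS,1.00,1.55,0.70,NA
ANA_BRA,1.20,0.95,0.90,NA
CCA,1.00,1.55,NA,NA
MACROBORER,NA,NA,NA,NA
TURF,NA,NA,NA,NA
SAND,NA,NA,NA,NA
CHL_SOR,NA,NA,NA,5.5
SCA_DIM,NA,NA,NA,5.0
SCA_PSI,NA,NA,NA,5.2
CET_BIC,NA,NA,NA,4.5
BOL_MUR,NA,NA,NA,8.0
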