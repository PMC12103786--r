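study_id,p_rct,p_rwe,c,medicare,p_ttr_printed,p_s_printed
LEADER,<0.0001,<0.0001,2.6,TRUE,<0.0001,<0.0001
DECLARE,<0.0001,<0.0001,0.7,TRUE,<0.0001,<0.0001
EMPA-REG,<0.0001,<0.0001,1.2,TRUE,<0.0001,<0.0001
CANVAS,<0.0001,<0.0001,1.8,TRUE,<0.0001,<0.0001
CARMELINA,0.0003,<0.0001,4.2,TRUE,0.0003,<0.0001
TECOS,<0.0001,<0.0001,14.3,TRUE,<0.0001,<0.0001
SAVOR-TIMI,<0.0001,<0.0001,3.5,TRUE,<0.0001,<0.0001
TRITON-TIMI,<0.0001,0.007,1.0,FALSE,0.007,0.003
PLATO,<0.0001,0.056,0.7,FALSE,0.056,0.031
ARISTOTLE,<0.0001,<0.0001,2.7,TRUE,<0.0001,<0.0001
RE-LY,<0.0001,<0.0001,1.2,TRUE,<0.0001,<0.0001
ROCKET-AF,<0.0001,<0.0001,2.2,TRUE,<0.0001,<0.0001
EINSTEIN-DVT,<0.0001,<0.0001,5.3,TRUE,<0.0001,<0.0001
EINSTEIN-PE,0.0018,<0.0001,4.4,TRUE,0.0018,<0.0001
RECOVER II,0.0002,<0.0001,1.4,TRUE,0.0002,0.0002
AMPLIFY,<0.0001,<0.0001,0.7,TRUE,<0.0001,<0.0001
RECORD1,<0.0001,<0.0001,1.3,TRUE,<0.0001,<0.0001
TRANSCEND,0.10,0.002,2.3,FALSE,0.10,0.064
ON-TARGET,0.001,<0.0001,0.9,FALSE,0.001,<0.0001
HORIZON-PIVOTAL,0.001,0.014,1.8,FALSE,0.014,0.01
DAPA-CKD,<0.0001,0.16,0.2,TRUE,0.16,0.15
PARADIGM-HF,<0.0001,0.63,0.6,TRUE,0.63,0.65
P04334,<0.0001,0.015,1.2,FALSE,0.015,0.004
D5896,0.002,0.046,1.0,FALSE,0.046,0.03
IMPACT,<0.0001,1.00,0.5,FALSE,1.00,1.00
POET-COPD,<0.0001,0.66,0.7,FALSE,0.66,0.68
INSPIRE,0.34,<0.0001,19.9,FALSE,0.34,0.25
CAROLINA,0.0001,<0.0001,1.2,TRUE,0.0001,<0.0001
PRONOUNCE,0.73,0.95,4.7,TRUE,0.95,NA
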